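#' Read a candidate-region file
#'
#' The file is a header-less or headered TSV with columns `chrom`, `start`,
#' `end`, `name`, `window_bp`. Coordinates are 1-based and fully inclusive
#' (note: this differs from standard BED, which is 0-based half-open).
#' `start == end` encodes a point marker. `window_bp` is the symmetric
#' extension applied around the anchor, e.g. 1e6 for a strongly replicated
#' candidate gene, 5e5 around a linkage-map microsatellite marker, 5e4
#' around other candidate genes.
#'
#' @param path Path to the TSV; a header line `chrom start end ...` is
#'   detected and honored.
#' @return A tibble of regions with the five columns above, validated.
#' @export
read_regions <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- length(first) && grepl("^chrom\t", first)
  regions <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("chrom", "start", "end", "name", "window_bp"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      name = readr::col_character(),
      window_bp = readr::col_double()
    ),
    skip = 0, progress = FALSE
  )
  if (!all(c("chrom", "start", "end", "name", "window_bp") %in% names(regions))) {
    abort("Region file must have columns chrom, start, end, name, window_bp.")
  }
  validate_regions(regions, offset = if (has_header) 1L else 0L)
  regions
}

validate_regions <- function(regions, offset = 0L) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      abort(sprintf("Region file line %d: %s.", i[1] + offset, what))
    }
  }
  bad(is.na(regions$start) | is.na(regions$end) | is.na(regions$window_bp) |
        is.na(regions$chrom), "malformed line")
  bad(regions$start < 1, "start must be >= 1")
  bad(regions$end < regions$start, "end < start")
  bad(regions$window_bp < 0, "negative window_bp")
  invisible(regions)
}

#' Write a candidate-region file
#'
#' @param regions Tibble of regions as produced by [read_regions()] or
#'   [simulate_regions()].
#' @param path Output path (TSV with header).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  readr::write_tsv(regions, path, progress = FALSE)
  invisible(path)
}

#' Effective (window-extended) intervals of candidate regions
#'
#' @param regions Region tibble.
#' @return The tibble with `lo`/`hi` columns:
#'   `[max(1, start - window_bp), end + window_bp]`, 1-based inclusive.
#' @export
region_intervals <- function(regions) {
  dplyr::mutate(
    regions,
    lo = pmax(1, .data$start - .data$window_bp),
    hi = .data$end + .data$window_bp
  )
}

#' Partition panel SNPs into prioritized and non-prioritized subsets
#'
#' A SNP is prioritized if and only if its position lies within the
#' window-extended interval of at least one region on the same chromosome;
#' both interval boundaries are inclusive, so a SNP exactly
#' `window_bp` away from an anchor boundary is prioritized. Overlapping
#' regions are implicitly unioned; a SNP matched by several regions appears
#' once with every match recorded. The two subsets are disjoint and
#' exhaustive.
#'
#' @param panel A [genotype_panel()].
#' @param regions Region tibble (see [read_regions()]); an empty tibble
#'   yields an all-non-prioritized assignment.
#' @return A tibble with one row per SNP in panel order: `snp_id`,
#'   `prioritized` (logical), `matched_regions` (semicolon-joined region
#'   names, `""` when none).
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_snps = 10, seed = 2))
#' regions <- tibble::tibble(chrom = "1", start = 2001, end = 4001,
#'                           name = "geneA", window_bp = 0)
#' assign_subsets(panel, regions)
assign_subsets <- function(panel, regions) {
  stopifnot(inherits(panel, "genotype_panel"))
  validate_regions(regions)
  ivs <- region_intervals(regions)
  matches <- vector("list", n_snps(panel))
  for (r in seq_len(nrow(ivs))) {
    hit <- panel$map$chrom == ivs$chrom[r] &
      panel$map$pos >= ivs$lo[r] & panel$map$pos <= ivs$hi[r]
    for (i in which(hit)) matches[[i]] <- c(matches[[i]], ivs$name[r])
  }
  tibble::tibble(
    snp_id = panel$map$snp_id,
    prioritized = lengths(matches) > 0,
    matched_regions = purrr::map_chr(matches, \(x) paste(x, collapse = ";"))
  )
}
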