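#' Parse a target interval list
#'
#' Reads the panel's target interval list: one interval per line in the form
#' `chrom:start-end` (or `chrom:pos` for single-base targets), optionally
#' followed by a tab and a group/exon label such as `TP53_Exon1`. Coordinates
#' are 1-based inclusive, matching GATK interval notation. When the label is
#' absent it is auto-generated as `chrom_start`.
#'
#' @param path Path to the interval list file.
#' @param x_chrom_name Chromosome names treated as the X chromosome.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`, `rank`
#'   (0-based position in file order) and `is_x`.
#' @export
parse_interval_list <- function(path, x_chrom_name = c("X", "chrX")) {
  if (!file.exists(path)) {
    abort(paste0("interval list not found: ", path), class = "panelcnv_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("interval list is empty", class = "panelcnv_input_error")
  }
  parts <- stringr::str_split_fixed(lines, "\t", 2L)
  coords <- parse_targets(parts[, 1L], context = "interval list")
  labels <- trimws(parts[, 2L])
  labels <- ifelse(nzchar(labels), labels, paste0(coords$chrom, "_", coords$start))
  bad <- which(coords$start > coords$end)
  if (length(bad) > 0L) {
    abort(
      sprintf("interval list line %d: start > end (%s)", bad[1L], parts[bad[1L], 1L]),
      class = "panelcnv_validation_error"
    )
  }
  tibble(
    chrom = coords$chrom,
    start = coords$start,
    end = coords$end,
    label = labels,
    rank = seq_along(lines) - 1L,
    is_x = coords$chrom %in% x_chrom_name
  )
}

# Parse "chrom:start-end" / "chrom:pos" target strings into a tibble of
# chrom/start/end. Errors carry the 1-based index of the first bad entry.
parse_targets <- function(targets, context = "target") {
  m <- stringr::str_match(trimws(targets), "^([^:]+):(\\d+)(?:-(\\d+))?$")
  bad <- which(is.na(m[, 1L]))
  if (length(bad) > 0L) {
    abort(
      sprintf("%s line %d: malformed coordinate '%s'", context, bad[1L], targets[bad[1L]]),
      class = "panelcnv_parse_error"
    )
  }
  start <- as.integer(m[, 3L])
  end <- ifelse(is.na(m[, 4L]), start, as.integer(m[, 4L]))
  tibble(chrom = m[, 2L], start = start, end = as.integer(end))
}

# canonical "chrom:start-end" key used to match summary rows to the list
target_key <- function(chrom, start, end) {
  paste0(chrom, ":", start, "-", end)
}

check_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end", "label", "rank", "is_x") %in% names(intervals)))
  if (any(duplicated(intervals$rank)) ||
      !identical(sort(intervals$rank), seq_len(nrow(intervals)) - 1L)) {
    abort("interval ranks must be dense 0..n-1", class = "panelcnv_validation_error")
  }
  invisible(intervals)
}
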