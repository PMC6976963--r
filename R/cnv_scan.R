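#' Exon-coverage quality control
#'
#' A region is retained iff its length strictly exceeds `min_length` (45 bp)
#' and its mean depth lies inside `[min_depth, max_depth]` (30-800 reads/bp,
#' bounds inclusive) in every one of the 13 samples.
#'
#' @param coverage Tibble (`region_id`, `condition`, `depth`).
#' @param regions Region tibble with `region_id` and `length`.
#' @param min_depth,max_depth,min_length QC thresholds.
#' @return List: `retained` (region_id vector) and `report` (tibble of
#'   kept/dropped counts per reason; a region failing both reasons is tallied
#'   under the length rule).
#' @export
filter_regions <- function(coverage, regions, min_depth = 30,
                           max_depth = 800, min_length = 45) {
  check_conditions_present(coverage$condition, "coverage table")
  depth_ok <- coverage %>%
    dplyr::group_by(.data$region_id) %>%
    dplyr::summarise(
      depth_ok = all(.data$depth >= min_depth & .data$depth <= max_depth),
      .groups = "drop"
    )
  status <- regions %>%
    dplyr::select("region_id", "length") %>%
    dplyr::inner_join(depth_ok, by = "region_id") %>%
    dplyr::mutate(
      length_ok = .data$length > min_length,
      verdict = dplyr::case_when(
        !length_ok ~ "dropped_length",
        !depth_ok ~ "dropped_depth",
        TRUE ~ "kept"
      )
    )
  list(
    retained = status$region_id[status$verdict == "kept"],
    report = status %>% dplyr::count(.data$verdict, name = "n_regions")
  )
}

#' Library-size normalization and common-reference copy-number ratios
#'
#' Each sample's depths are first rescaled by (mean library size / sample
#' library size); each region's rescaled depths are then divided by their
#' across-sample mean (the common reference built from all samples), so every
#' region's normalized values average exactly 1 across the 13 samples.
#'
#' @param coverage Tibble (`region_id`, `condition`, `depth`).
#' @param library_sizes Tibble (`condition`, `library_size`), all positive.
#' @param retained Region ids to keep (from [filter_regions()]).
#' @return Tibble (`region_id`, `condition`, `normalized`).
#' @export
normalize_copy_number <- function(coverage, library_sizes, retained) {
  if (length(retained) == 0) abort("no retained regions to normalize")
  if (any(library_sizes$library_size <= 0)) {
    abort("library sizes must be positive")
  }
  mean_lib <- mean(library_sizes$library_size)
  out <- coverage %>%
    dplyr::filter(.data$region_id %in% retained) %>%
    dplyr::left_join(library_sizes, by = "condition") %>%
    dplyr::mutate(scaled = .data$depth * mean_lib / .data$library_size) %>%
    dplyr::group_by(.data$region_id) %>%
    dplyr::mutate(.ref = mean(.data$scaled)) %>%
    dplyr::ungroup()
  if (any(out$.ref <= 0)) {
    abort(sprintf("region %s has zero mean scaled depth",
                  out$region_id[which(out$.ref <= 0)[1]]))
  }
  out %>%
    dplyr::mutate(normalized = .data$scaled / .data$.ref) %>%
    dplyr::select("region_id", "condition", "normalized")
}

#' Per-gene normalized and centre-reduced copy-number profiles
#'
#' Region-level normalized values are averaged (unweighted) per gene and
#' condition, then centre-reduced across the 13 conditions: subtract the
#' profile mean and divide by its population standard deviation (denominator
#' n). Genes whose across-condition spread is below `1e-12` are flagged
#' degenerate and given all-zero z values; genes with no retained region are
#' excluded (with a message).
#'
#' @param normalized Output of [normalize_copy_number()].
#' @param regions Region tibble mapping `region_id` to `gene_id`.
#' @param genes Gene annotation tibble (`gene_id`, ...); genes absent from it
#'   are still profiled.
#' @return Tibble (`gene_id`, `condition`, `normalized`, `z`, `degenerate`).
#' @export
gene_profiles <- function(normalized, regions, genes = NULL) {
  mapped <- normalized %>%
    dplyr::left_join(regions %>% dplyr::select("region_id", "gene_id"),
                     by = "region_id")
  if (any(is.na(mapped$gene_id))) {
    abort("every retained exon region must map to one gene")
  }
  if (!is.null(genes)) {
    lost <- setdiff(genes$gene_id, unique(mapped$gene_id))
    if (length(lost) > 0) {
      inform(sprintf("%d gene(s) had no retained region and were excluded",
                     length(lost)))
    }
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mapped %>%
    dplyr::group_by(.data$gene_id, .data$condition) %>%
    dplyr::summarise(normalized = mean(.data$normalized), .groups = "drop") %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(
      .sd = pop_sd(.data$normalized),
      degenerate = .data$.sd < 1e-12,
      z = dplyr::if_else(.data$degenerate, 0,
                         (.data$normalized - mean(.data$normalized)) /
                           .data$.sd)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("gene_id", "condition", "normalized", "z", "degenerate")
}

#' Per-line CNV-association pass rule
#'
#' A gene passes for a line iff, on the chosen profile scale `v`,
#' `(v[F0_LD80] - v[F0]) > t1` AND `(v[F0_LD80] - v[F2]) > 0` AND
#' `((v[F2_LD25] - v[F2]) > t2 OR (v[F2_LD75] - v[F2]) > t2)`, all
#' inequalities strict. Degenerate profiles never pass. The thresholds were
#' stated for centre-reduced profiles (`scale = "z"`, the default); the
#' normalized-ratio scale is the appropriate choice when non-amplified genes
#' are expected to sit flat at the diploid baseline, as in synthetic data
#' (see the methods vignette).
#'
#' @param profiles Output of [gene_profiles()].
#' @param line `"Delt"`, `"Bend"` or `"Feni"`.
#' @param t1,t2 Pass-rule thresholds (strict, > 0).
#' @param scale `"z"` (centre-reduced) or `"ratio"` (normalized values).
#' @return Tibble (`gene_id`, `line`, `pass`, and the five profile values
#'   used).
#' @export
call_cnv_association <- function(profiles, line, t1 = 0.3, t2 = 0.2,
                                 scale = c("z", "ratio")) {
  scale <- match.arg(scale)
  if (t1 <= 0 || t2 <= 0) abort("t1 and t2 must be > 0")
  conds <- line_conditions(line)
  value_col <- if (scale == "z") "z" else "normalized"
  wide <- profiles %>%
    dplyr::filter(.data$condition %in% conds) %>%
    dplyr::select("gene_id", "condition", "degenerate",
                  value = dplyr::all_of(value_col)) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  missing <- setdiff(conds, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("profiles are missing condition(s): %s",
                  paste(missing, collapse = ", ")))
  }
  v <- function(stage) wide[[condition_label(line, stage)]]
  if (anyNA(c(v("F0"), v("F0_LD80"), v("F2"), v("F2_LD25"), v("F2_LD75")))) {
    abort("some genes lack values for the line's five conditions")
  }
  wide %>%
    dplyr::mutate(
      line = line,
      pass = !.data$degenerate &
        (v("F0_LD80") - v("F0")) > t1 &
        (v("F0_LD80") - v("F2")) > 0 &
        ((v("F2_LD25") - v("F2")) > t2 | (v("F2_LD75") - v("F2")) > t2)
    ) %>%
    dplyr::select("gene_id", "line", "pass", dplyr::all_of(conds))
}

#' Full CNV scan: QC, normalization, profiles and per-line calls
#'
#' @inheritParams filter_regions
#' @inheritParams normalize_copy_number
#' @param genes Gene annotation tibble.
#' @param t1,t2,scale Passed to [call_cnv_association()].
#' @return List with `profiles`, `calls` (all three lines bound), `qc_report`
#'   and `retained`.
#' @export
cnv_scan <- function(coverage, regions, library_sizes, genes = NULL,
                     min_depth = 30, max_depth = 800, min_length = 45,
                     t1 = 0.3, t2 = 0.2, scale = c("z", "ratio")) {
  scale <- match.arg(scale)
  qc <- filter_regions(coverage, regions, min_depth, max_depth, min_length)
  normalized <- normalize_copy_number(coverage, library_sizes, qc$retained)
  profiles <- gene_profiles(normalized, regions, genes)
  calls <- dplyr::bind_rows(lapply(
    line_levels(),
    function(l) call_cnv_association(profiles, l, t1, t2, scale) %>%
      dplyr::select("gene_id", "line", "pass")
  ))
  list(profiles = profiles, calls = calls, qc_report = qc$report,
       retained = qc$retained)
}
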