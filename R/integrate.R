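#' Selection regions from dual-contrast scan evidence and trajectory hits
#'
#' A region is seeded by every trajectory-filter hit whose locus reaches
#' `q < q_threshold` in both the F0 and the F2 scan of its line. Each seed
#' opens a window of +/- `window_bp` around the locus; overlapping windows of
#' one line on one chromosome are merged. Regions containing at least one
#' candidate gene (any annotated family other than `"other"`) list them;
#' regions with none are retained and flagged `anonymous`.
#'
#' @param hits Trajectory-filter output ([trajectory_filter()]) with
#'   `verdict != "none"` rows considered.
#' @param scan_f0,scan_f2 `fst_scan` objects (or their tidied tibbles) of
#'   the same line's two contrasts.
#' @param genes Gene annotation tibble (0-based half-open `start`, `end`).
#' @param window_bp Window half-width (default 50,000).
#' @param q_threshold Significance threshold on both contrasts' q-values.
#' @return Tibble (`chrom`, `start`, `end`, `line`, `n_loci`, `loci`,
#'   `min_q_f0`, `min_q_f2`, `candidate_genes`, `anonymous`), 0-based
#'   half-open.
#' @export
select_regions <- function(hits, scan_f0, scan_f2, genes,
                           window_bp = 5e4, q_threshold = 0.05) {
  as_result <- function(x) if (inherits(x, "fst_scan")) x$result else x
  f0 <- as_result(scan_f0) %>%
    dplyr::select("chrom", "pos", q_f0 = "q")
  f2 <- as_result(scan_f2) %>%
    dplyr::select("chrom", "pos", q_f2 = "q")
  line <- unique(hits$line[hits$verdict != "none"])
  seeds <- hits %>%
    dplyr::filter(.data$verdict != "none") %>%
    dplyr::inner_join(f0, by = c("chrom", "pos")) %>%
    dplyr::inner_join(f2, by = c("chrom", "pos")) %>%
    dplyr::filter(!is.na(.data$q_f0), !is.na(.data$q_f2),
                  .data$q_f0 < q_threshold, .data$q_f2 < q_threshold)
  empty <- tibble::tibble(
    chrom = character(), start = double(), end = double(),
    line = character(), n_loci = integer(), loci = character(),
    min_q_f0 = double(), min_q_f2 = double(),
    candidate_genes = character(), anonymous = logical()
  )
  if (nrow(seeds) == 0) return(empty)
  candidates <- genes %>% dplyr::filter(.data$family != "other")
  out <- seeds %>%
    dplyr::mutate(w_start = pmax(0, .data$pos - 1 - window_bp),
                  w_end = .data$pos + window_bp) %>%
    dplyr::group_by(.data$line, .data$chrom) %>%
    dplyr::arrange(.data$w_start, .by_group = TRUE) %>%
    dplyr::mutate(cluster = cumsum(
      .data$w_start > dplyr::lag(cummax(.data$w_end),
                                 default = -Inf)
    )) %>%
    dplyr::group_by(.data$line, .data$chrom, .data$cluster) %>%
    dplyr::summarise(
      start = min(.data$w_start), end = max(.data$w_end),
      n_loci = dplyr::n(),
      loci = paste(sprintf("%s:%d", .data$chrom, .data$pos),
                   collapse = ","),
      min_q_f0 = min(.data$q_f0), min_q_f2 = min(.data$q_f2),
      .groups = "drop"
    ) %>%
    dplyr::select(-"cluster")
  out$candidate_genes <- vapply(seq_len(nrow(out)), function(i) {
    g <- candidates[candidates$chrom == out$chrom[i] &
                      candidates$start < out$end[i] &
                      candidates$end > out$start[i], ]
    paste(g$gene_id, collapse = ",")
  }, character(1))
  out %>%
    dplyr::mutate(anonymous = .data$candidate_genes == "") %>%
    dplyr::select("chrom", "start", "end", "line", "n_loci", "loci",
                  "min_q_f0", "min_q_f2", "candidate_genes", "anonymous")
}

#' Venn overlap counts of per-line hit sets
#'
#' @param sets Named list of three character vectors (names `Delt`, `Bend`,
#'   `Feni` by convention).
#' @return Tibble with one row per non-empty membership class (7 rows) and
#'   its count.
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3) abort("venn_counts expects exactly three sets")
  nm <- names(sets)
  all_items <- unique(unlist(sets))
  classes <- tidyr::expand_grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                                c = c(TRUE, FALSE)) %>%
    dplyr::filter(.data$a | .data$b | .data$c)
  member <- tibble::tibble(
    item = all_items,
    a = all_items %in% sets[[1]],
    b = all_items %in% sets[[2]],
    c = all_items %in% sets[[3]]
  )
  classes %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      class = paste(c(nm[1], nm[2], nm[3])[c(.data$a, .data$b, .data$c)],
                    collapse = "&"),
      n = sum(member$a == .data$a & member$b == .data$b &
                member$c == .data$c)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("class", "n")
}

#' Nonsynonymous and frameshift hits on candidate genes
#'
#' Restricts trajectory-filter hits to protein-altering variants
#' (`nonsynonymous` or `frameshift`) whose gene belongs to a candidate family
#' (anything but `"other"`), attaches the five-stage frequency profile and
#' flags co-location within a selection region.
#'
#' @param hits Trajectory-filter output with `effect` and the `f_*` columns.
#' @param genes Gene annotation tibble.
#' @param regions Selection regions ([select_regions()]), possibly from
#'   several lines bound together.
#' @return Tibble of protein-altering hits with `gene_id`, `family`,
#'   `in_selection_region` and the frequency profile.
#' @export
nonsyn_table <- function(hits, genes, regions) {
  prot <- hits %>%
    dplyr::filter(.data$verdict != "none",
                  .data$effect %in% c("nonsynonymous", "frameshift"))
  if (nrow(prot) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), line = character(),
      effect = character(), verdict = character(), gene_id = character(),
      family = character(), f_F0 = double(), f_F0_LD80 = double(),
      f_F2 = double(), f_F2_LD25 = double(), f_F2_LD75 = double(),
      in_selection_region = logical()
    ))
  }
  cand <- genes %>% dplyr::filter(.data$family != "other")
  prot$gene_id <- vapply(seq_len(nrow(prot)), function(i) {
    g <- cand[cand$chrom == prot$chrom[i] &
                prot$pos[i] - 1 >= cand$start &
                prot$pos[i] - 1 < cand$end, ]
    if (nrow(g) == 0) NA_character_ else g$gene_id[1]
  }, character(1))
  prot <- prot %>% dplyr::filter(!is.na(.data$gene_id)) %>%
    dplyr::left_join(genes %>% dplyr::select("gene_id", "family"),
                     by = "gene_id")
  prot$in_selection_region <- vapply(seq_len(nrow(prot)), function(i) {
    any(regions$line == prot$line[i] & regions$chrom == prot$chrom[i] &
          prot$pos[i] - 1 >= regions$start & prot$pos[i] - 1 < regions$end)
  }, logical(1))
  prot %>%
    dplyr::select("chrom", "pos", "line", "effect", "verdict", "gene_id",
                  "family", "f_F0", "f_F0_LD80", "f_F2", "f_F2_LD25",
                  "f_F2_LD75", "in_selection_region")
}

#' Evaluate pipeline calls against simulator ground truth
#'
#' For each evidence stream, compares the calls with the simulated causal
#' loci: sensitivity (causal loci recovered in their line), false-positive
#' count, false-discovery rate and the enrichment of the causal hit rate
#' over the neutral hit rate (infinite when no neutral locus is hit).
#'
#' @param calls Tibble of calls with columns `id` and `line`.
#' @param truth Tibble with columns `id`, `line` (line whose insecticide the
#'   locus affects, `NA` for neutral loci) and `causal` (logical).
#' @param stream Label for the output row.
#' @return One-row tibble (`stream`, `n_causal`, `n_called`, `tp`,
#'   `false_positives`, `sensitivity`, `fdr`, `enrichment`).
#' @export
truth_eval <- function(calls, truth, stream = "calls") {
  if (!all(calls$id %in% truth$id)) {
    abort("calls contain ids absent from the truth table")
  }
  causal <- truth %>% dplyr::filter(.data$causal)
  n_causal <- nrow(causal)
  tp <- sum(paste(calls$id, calls$line) %in%
              paste(causal$id, causal$line))
  fp <- nrow(calls) - sum(calls$id %in% causal$id)
  n_neutral <- sum(!truth$causal)
  neutral_rate <- if (n_neutral > 0) {
    length(unique(calls$id[!calls$id %in% causal$id])) / n_neutral
  } else {
    NA_real_
  }
  sens <- if (n_causal > 0) tp / n_causal else NA_real_
  tibble::tibble(
    stream = stream, n_causal = n_causal, n_called = nrow(calls), tp = tp,
    false_positives = fp,
    sensitivity = sens,
    fdr = if (nrow(calls) > 0) fp / nrow(calls) else 0,
    enrichment = if (!is.na(neutral_rate) && neutral_rate > 0) {
      sens / neutral_rate
    } else if (!is.na(sens) && sens > 0) Inf else NA_real_
  )
}
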