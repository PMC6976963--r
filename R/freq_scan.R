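#' Pool allele frequencies from read counts
#'
#' `f = alt / (ref + alt)` per locus and condition. Stages with depth below
#' `low_coverage_depth` are flagged; zero-depth stages get an undefined
#' frequency (`NA`) and are excluded from downstream filtering.
#'
#' @param counts Long count tibble ([read_allele_counts()]).
#' @param low_coverage_depth Depth below which a stage is flagged
#'   (default 30).
#' @return Tibble (`chrom`, `pos`, `ref`, `alt`, `effect`, `condition`,
#'   `depth`, `freq`, `flagged`).
#' @export
estimate_frequencies <- function(counts, low_coverage_depth = 30) {
  counts %>%
    dplyr::mutate(
      depth = .data$ref_reads + .data$alt_reads,
      freq = dplyr::if_else(.data$depth > 0,
                            .data$alt_reads / .data$depth, NA_real_),
      flagged = .data$depth < low_coverage_depth
    ) %>%
    dplyr::select("chrom", "pos", "ref", "alt", "effect", "condition",
                  "depth", "freq", "flagged")
}

#' Five-stage frequency trajectories per line
#'
#' Spreads [estimate_frequencies()] output into one row per locus and line
#' with the five stage frequencies `f_F0 ... f_F2_LD75` and a
#' `flagged` indicator (any stage with low or zero coverage).
#'
#' @inheritParams estimate_frequencies
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `effect`,
#'   `line`, `f_F0`, `f_F0_LD80`, `f_F2`, `f_F2_LD25`, `f_F2_LD75`,
#'   `flagged`.
#' @export
frequency_trajectories <- function(counts, low_coverage_depth = 30) {
  freqs <- estimate_frequencies(counts, low_coverage_depth)
  cond_map <- condition_table() %>% dplyr::select("condition", "stage")
  rows <- lapply(line_levels(), function(ln) {
    freqs %>%
      dplyr::filter(.data$condition %in% line_conditions(ln)) %>%
      dplyr::left_join(cond_map, by = "condition") %>%
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
                      .data$effect) %>%
      dplyr::summarise(
        line = .env$ln,
        f_F0 = .data$freq[.data$stage == "F0"],
        f_F0_LD80 = .data$freq[.data$stage == "F0_LD80"],
        f_F2 = .data$freq[.data$stage == "F2"],
        f_F2_LD25 = .data$freq[.data$stage == "F2_LD25"],
        f_F2_LD75 = .data$freq[.data$stage == "F2_LD75"],
        flagged = any(.data$flagged) | anyNA(.data$freq),
        .groups = "drop"
      )
  })
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$line)
}

#' Variant quality-control filter
#'
#' A locus is retained iff its depth strictly exceeds `min_depth` in all 13
#' conditions, its largest between-condition frequency difference is at least
#' `min_freq_diff` (it is polymorphic among the conditions), and its minor
#' allele reaches at least `min_support` of the reads in at least one
#' condition.
#'
#' @inheritParams estimate_frequencies
#' @param min_depth,min_support,min_freq_diff QC thresholds (defaults 30,
#'   0.04, 0.05).
#' @return List: `retained` (locus tibble `chrom`, `pos`) and `report`
#'   (drop tallies per reason; the first failing rule in the order
#'   depth / polymorphism / support is tallied).
#' @export
qc_filter_variants <- function(counts, min_depth = 30, min_support = 0.04,
                               min_freq_diff = 0.05) {
  check_conditions_present(counts$condition, "count table")
  status <- estimate_frequencies(counts, min_depth) %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::summarise(
      depth_ok = all(.data$depth > min_depth),
      poly_ok = {
        f <- .data$freq[!is.na(.data$freq)]
        length(f) > 0 && (max(f) - min(f)) >= min_freq_diff
      },
      support_ok = any(pmin(.data$freq, 1 - .data$freq) >= min_support,
                       na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::mutate(verdict = dplyr::case_when(
      !depth_ok ~ "dropped_depth",
      !poly_ok ~ "dropped_monomorphic",
      !support_ok ~ "dropped_support",
      TRUE ~ "kept"
    ))
  list(
    retained = status %>% dplyr::filter(.data$verdict == "kept") %>%
      dplyr::select("chrom", "pos"),
    report = status %>% dplyr::count(.data$verdict, name = "n_loci")
  )
}

#' Frequency-band specification of the trajectory filter
#'
#' Initial-frequency bands with the minimum F0 to F0_LD80 rise required in
#' each: the deltamethrin line's lowest band starts at 0.30 (its founder
#' population is more resistant), the bendiocarb and fenitrothion lines' at
#' 0.15; all lines then share `[0.85, 0.90) -> +0.10`, `[0.90, 0.95) ->
#' +0.05` and `[0.95, 1] -> any increase`. Bands are left-closed
#' right-open except the closed top band. The same minimum applies to the F2
#' to F2_LD75 rise.
#'
#' @return Tibble (`line`, `band_lo`, `band_hi`, `delta`, `top`), with
#'   `delta = 0` and `top = TRUE` meaning any strict increase.
#' @export
trajectory_filter_spec <- function() {
  per_line <- function(line, floor0) {
    tibble::tibble(
      line = line,
      band_lo = c(floor0, 0.85, 0.90, 0.95),
      band_hi = c(0.85, 0.90, 0.95, 1),
      delta = c(0.15, 0.10, 0.05, 0),
      top = c(FALSE, FALSE, FALSE, TRUE)
    )
  }
  dplyr::bind_rows(per_line("Delt", 0.30),
                   per_line("Bend", 0.15),
                   per_line("Feni", 0.15))
}

# verdict for one direction of travel given stage frequency vectors
trajectory_pass_band <- function(f0, f80, f2, f25, f75, line, spec) {
  bands <- spec[spec$line == line, , drop = FALSE]
  band <- rep(NA_integer_, length(f0))
  for (b in seq_len(nrow(bands))) {
    inb <- f0 >= bands$band_lo[b] &
      (if (bands$top[b]) f0 <= bands$band_hi[b] else f0 < bands$band_hi[b])
    band[is.na(band) & inb] <- b
  }
  delta <- ifelse(is.na(band), NA_real_, bands$delta[band])
  rise <- f80 - f0
  final <- f75 - f2
  ok <- !is.na(band) &
    ifelse(delta > 0, rise >= delta, rise > 0) &
    f2 < f80 &
    f25 > f2 &
    f75 > f25 &
    ifelse(delta > 0, final >= delta, final > 0)
  list(ok = ok & !is.na(ok), band = band)
}

#' Allele-frequency trajectory filter
#'
#' Classifies each locus x line trajectory as `resistance`, `deleterious` or
#' `none`. A trajectory is resistance-associated iff its initial frequency
#' falls in one of the line's bands, the F0 to F0_LD80 rise meets the band's
#' minimum, the frequency then drops from F0_LD80 to F2 (outcrossing with the
#' susceptible strain), rises from F2 to F2_LD25 and again to F2_LD75, and
#' the F2 to F2_LD75 rise meets the band's minimum. A trajectory is
#' deleterious iff its complement (`1 - f` at every stage) is
#' resistance-associated; the two verdicts are mutually exclusive. Flagged
#' trajectories (any low- or zero-coverage stage) return `none` with reason
#' `"low_coverage"`.
#'
#' @param traj Trajectory tibble from [frequency_trajectories()] (columns
#'   `line`, `f_F0` ... `f_F2_LD75`, optional `flagged`).
#' @param spec Band table ([trajectory_filter_spec()]).
#' @return `traj` with `verdict`, `band` (matched band label, on the allele's
#'   own scale for resistance, the complement's for deleterious) and
#'   `reason` columns.
#' @export
trajectory_filter <- function(traj, spec = trajectory_filter_spec()) {
  flagged <- if ("flagged" %in% names(traj)) traj$flagged else
    rep(FALSE, nrow(traj))
  flagged <- flagged | !complete.cases(
    traj[, c("f_F0", "f_F0_LD80", "f_F2", "f_F2_LD25", "f_F2_LD75")]
  )
  res <- del <- list(ok = rep(FALSE, nrow(traj)),
                     band = rep(NA_integer_, nrow(traj)))
  for (line in unique(traj$line)) {
    i <- which(traj$line == line & !flagged)
    if (length(i) == 0) next
    r <- trajectory_pass_band(traj$f_F0[i], traj$f_F0_LD80[i], traj$f_F2[i],
                              traj$f_F2_LD25[i], traj$f_F2_LD75[i],
                              line, spec)
    d <- trajectory_pass_band(1 - traj$f_F0[i], 1 - traj$f_F0_LD80[i],
                              1 - traj$f_F2[i], 1 - traj$f_F2_LD25[i],
                              1 - traj$f_F2_LD75[i], line, spec)
    res$ok[i] <- r$ok; res$band[i] <- r$band
    del$ok[i] <- d$ok; del$band[i] <- d$band
  }
  labels <- spec %>%
    dplyr::group_by(.data$line) %>%
    dplyr::mutate(b = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(label = sprintf("[%.2f,%.2f%s", .data$band_lo,
                                  .data$band_hi,
                                  ifelse(.data$top, "]", ")")))
  band_label <- function(b, line) {
    key <- paste(line, b)
    labels$label[match(key, paste(labels$line, labels$b))]
  }
  traj %>%
    dplyr::mutate(
      verdict = dplyr::case_when(
        flagged ~ "none",
        res$ok ~ "resistance",
        del$ok ~ "deleterious",
        TRUE ~ "none"
      ),
      band = dplyr::case_when(
        res$ok & !flagged ~ band_label(res$band, .data$line),
        del$ok & !flagged ~ band_label(del$band, .data$line),
        TRUE ~ NA_character_
      ),
      reason = dplyr::if_else(flagged, "low_coverage", NA_character_)
    )
}

#' Per-line frequency report for named target-site loci
#'
#' Reports the read-based frequency trajectory (with low-coverage flags) of
#' named loci, such as the kdr voltage-gated sodium channel mutations, one
#' row per locus x line x stage. Absent loci produce a warning and no rows.
#'
#' @param counts Long count tibble.
#' @param named_loci Tibble (`name`, `chrom`, `pos`).
#' @param low_coverage_depth Flagging depth (default 30).
#' @return Tibble (`name`, `chrom`, `pos`, `line`, `stage`, `condition`,
#'   `freq`, `depth`, `flagged`).
#' @export
kdr_report <- function(counts, named_loci, low_coverage_depth = 30) {
  freqs <- estimate_frequencies(counts, low_coverage_depth)
  present <- named_loci %>%
    dplyr::semi_join(freqs, by = c("chrom", "pos"))
  absent <- dplyr::anti_join(named_loci, present, by = c("chrom", "pos"))
  if (nrow(absent) > 0) {
    warn(sprintf("named locus(es) absent from counts: %s",
                 paste(absent$name, collapse = ", ")))
  }
  if (nrow(present) == 0) {
    return(tibble::tibble(name = character(), chrom = character(),
                          pos = integer(), line = character(),
                          stage = character(), condition = character(),
                          freq = double(), depth = double(),
                          flagged = logical()))
  }
  cond_map <- condition_table() %>% dplyr::select("condition", "stage")
  dplyr::bind_rows(lapply(line_levels(), function(ln) {
    present %>%
      dplyr::inner_join(freqs, by = c("chrom", "pos")) %>%
      dplyr::filter(.data$condition %in% line_conditions(ln)) %>%
      dplyr::left_join(cond_map, by = "condition") %>%
      dplyr::mutate(line = .env$ln) %>%
      dplyr::select("name", "chrom", "pos", "line", "stage", "condition",
                    "freq", "depth", "flagged")
  })) %>%
    dplyr::arrange(.data$name, .data$line)
}

#' Genic effect of a substitution or indel
#'
#' Labels loci by their coding consequence given a coding model: a tibble of
#' CDS records (`gene_id`, `chrom`, `start`, `end` 0-based half-open,
#' `strand`, `seq` = spliced CDS sequence, 5' to 3'). Substitutions inside a
#' CDS are translated with the standard genetic code (synonymous /
#' nonsynonymous); length-changing variants are `frameshift` when the length
#' change is not a multiple of 3, otherwise `inframe_indel`. Loci within
#' `upstream_bp` of a gene start are `upstream`; everything else is
#' `intergenic`. With no coding model, positions are labelled by gene
#' proximity only.
#'
#' @param loci Tibble (`chrom`, `pos` 1-based, `ref`, `alt`).
#' @param cds Coding-model tibble, or `NULL`.
#' @param genes Gene annotation (used for upstream/intergenic labels).
#' @param upstream_bp Upstream window (default 1500).
#' @return `loci` with an `effect` column.
#' @export
annotate_effect <- function(loci, cds = NULL, genes = NULL,
                            upstream_bp = 1500) {
  n <- nrow(loci)
  eff <- rep(NA_character_, n)
  if (!is.null(cds) && nrow(cds) > 0) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("effect annotation from a coding model requires Biostrings")
    }
    code <- Biostrings::GENETIC_CODE
    for (j in seq_len(nrow(cds))) {
      seq <- toupper(cds$seq[j])
      if (nchar(seq) %% 3 != 0) {
        warn(sprintf("CDS of %s has length not a multiple of 3; skipped",
                     cds$gene_id[j]))
        next
      }
      hit <- which(loci$chrom == cds$chrom[j] &
                     loci$pos - 1 >= cds$start[j] &
                     loci$pos - 1 < cds$end[j] & is.na(eff))
      for (i in hit) {
        len_change <- nchar(loci$alt[i]) - nchar(loci$ref[i])
        if (len_change != 0) {
          eff[i] <- if (len_change %% 3 != 0) "frameshift" else
            "inframe_indel"
          next
        }
        if (nchar(loci$ref[i]) != 1) next # multi-base substitution: leave NA
        cds_pos <- if (identical(cds$strand[j], "-")) {
          cds$end[j] - loci$pos[i] + 1 # 1-based position within CDS
        } else {
          loci$pos[i] - cds$start[j]
        }
        base_ref <- toupper(loci$ref[i])
        base_alt <- toupper(loci$alt[i])
        if (identical(cds$strand[j], "-")) {
          comp <- c(A = "T", C = "G", G = "C", T = "A")
          base_ref <- comp[[base_ref]]
          base_alt <- comp[[base_alt]]
        }
        codon_i <- (cds_pos - 1) %/% 3
        within <- (cds_pos - 1) %% 3 + 1
        codon <- substr(seq, codon_i * 3 + 1, codon_i * 3 + 3)
        if (substr(codon, within, within) != base_ref) {
          warn(sprintf("reference mismatch at %s:%d in %s",
                       loci$chrom[i], loci$pos[i], cds$gene_id[j]))
        }
        mut <- codon
        substr(mut, within, within) <- base_alt
        eff[i] <- if (code[[codon]] == code[[mut]]) "synonymous" else
          "nonsynonymous"
      }
    }
  }
  if (!is.null(genes) && nrow(genes) > 0) {
    todo <- which(is.na(eff))
    for (i in todo) {
      up <- genes$chrom == loci$chrom[i] &
        loci$pos[i] - 1 >= genes$start - upstream_bp &
        loci$pos[i] - 1 < genes$start
      eff[i] <- if (any(up)) "upstream" else "intergenic"
    }
  }
  eff[is.na(eff)] <- "unknown"
  loci %>% dplyr::mutate(effect = eff)
}
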