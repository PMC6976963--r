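#' Design equally spaced intergenic capture targets
#'
#' Places fixed-size intergenic target regions along each contig with a greedy
#' left-to-right rule: starting 75.5 kb inside the contig, each next region is
#' placed at the usable position closest to the ideal 150 kb spacing from the
#' previous one, within a +/- 10 kb window; if no position in the window
#' passes all sequence filters the slot is skipped and the walk continues
#' another 150 kb on. A position is usable when its 220 bp window contains no
#' undefined base (N), has GC fraction <= 0.70 and a most-frequent-nucleotide
#' fraction <= 0.50, lies more than 5 kb from any annotated gene and more than
#' 75.5 kb from either contig end. Contigs shorter than 150 kb are skipped
#' entirely.
#'
#' @param genome A `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or a FASTA path.
#' @param genes Tibble with `chrom`, `start`, `end` (0-based half-open);
#'   may be empty. Contigs named in `genes` must exist in `genome`.
#' @param region_size,spacing,spacing_tol,gene_distance,max_gc,max_single,min_contig,edge_margin
#'   Design parameters (bp or fractions); defaults are the published panel
#'   criteria.
#' @return Tibble of regions (`region_id`, `chrom`, `start`, `end`,
#'   `kind = "intergenic"`, `gene_id = NA`, `length`), 0-based half-open.
#' @export
design_intergenic_targets <- function(genome, genes = NULL,
                                      region_size = 220L,
                                      spacing = 150000L,
                                      spacing_tol = 10000L,
                                      gene_distance = 5000L,
                                      max_gc = 0.70,
                                      max_single = 0.50,
                                      min_contig = 150000L,
                                      edge_margin = 75500L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("panel design requires the Biostrings package")
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer())
  }
  bad_contig <- setdiff(unique(genes$chrom), names(genome))
  if (length(bad_contig) > 0) {
    abort(sprintf("annotation contig(s) absent from genome: %s",
                  paste(bad_contig, collapse = ", ")))
  }
  out <- list()
  for (contig in names(genome)) {
    len <- Biostrings::width(genome[contig])
    if (len < min_contig) next
    first_start <- edge_margin
    last_start <- len - edge_margin - region_size
    if (last_start < first_start) next
    gsub_ <- genes[genes$chrom == contig, , drop = FALSE]
    placed <- integer(0)
    ideal <- first_start
    while (ideal <= last_start) {
      lo <- max(first_start, ideal - spacing_tol)
      hi <- min(last_start, ideal + spacing_tol)
      cand <- candidate_starts(genome[[contig]], lo, hi, region_size,
                               max_gc, max_single)
      if (length(cand) > 0 && nrow(gsub_) > 0) {
        ok <- vapply(cand, function(s) {
          !any(s < gsub_$end + gene_distance &
                 s + region_size > gsub_$start - gene_distance)
        }, logical(1))
        cand <- cand[ok]
      }
      if (length(cand) > 0) {
        pick <- cand[order(abs(cand - ideal), cand)][1]
        placed <- c(placed, pick)
        ideal <- pick + spacing
      } else {
        ideal <- ideal + spacing # slot unusable, keep walking
      }
    }
    if (length(placed) > 0) {
      out[[contig]] <- tibble::tibble(
        region_id = sprintf("%s_ig%03d", contig, seq_along(placed)),
        chrom = contig, start = placed, end = placed + region_size,
        kind = "intergenic", gene_id = NA_character_,
        length = region_size
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          kind = character(), gene_id = character(),
                          length = integer()))
  }
  dplyr::bind_rows(out)
}

# 0-based starts in [lo, hi] whose region_size window passes the sequence
# filters (no N, GC and single-nucleotide richness caps).
candidate_starts <- function(seq, lo, hi, region_size, max_gc, max_single) {
  window <- Biostrings::subseq(seq, start = lo + 1,
                               end = min(length(seq), hi + region_size))
  if (length(window) < region_size) return(integer(0))
  freq <- Biostrings::letterFrequencyInSlidingView(
    window, view.width = region_size, letters = c("A", "C", "G", "T")
  )
  n_views <- nrow(freq)
  starts <- lo + seq_len(n_views) - 1L
  keep <- starts <= hi
  freq <- freq[keep, , drop = FALSE]
  starts <- starts[keep]
  total <- rowSums(freq)
  no_n <- total == region_size
  gc <- (freq[, "C"] + freq[, "G"]) / region_size
  single <- apply(freq, 1, max) / region_size
  starts[no_n & gc <= max_gc & single <= max_single]
}
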