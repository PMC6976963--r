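#' Specify the simulated loci
#'
#' Builds the locus table consumed by the simulator. Each row is a biallelic
#' locus: an ordinary SNP (`locus_class = "snp"`) contributing
#' `beta_<line>` log10-dose units of tolerance per alt allele copy, or a
#' `"cnv_gene"` locus whose alt allele is a tandem amplification carrying
#' `cnv_copies` gene copies per haplotype (wild-type haplotypes carry one).
#'
#' @param chrom,pos Locus coordinates (`pos` 1-based).
#' @param locus_class `"snp"` or `"cnv_gene"`.
#' @param founder_freq Alt-allele frequency in the resistant founder
#'   composite, in `[0, 1]`.
#' @param susceptible_freq Alt-allele frequency in the susceptible strain
#'   (default 0: resistance alleles absent from the lab strain).
#' @param beta_Delt,beta_Bend,beta_Feni Tolerance shift (log10 dose) per alt
#'   allele copy for each insecticide.
#' @param cnv_copies Gene copies per amplification haplotype (integer >= 2)
#'   for `cnv_gene` loci; `NA` for SNPs.
#' @param dominance Heterozygote coefficient `h` (0.5 = additive).
#' @param effect Annotation label (`"intergenic"`, `"nonsynonymous"`, ...).
#' @param gene_id Gene carrying the locus (required for `cnv_gene`).
#' @param recomb Recombination fraction to the previous locus on the same
#'   chromosome (0.5 = unlinked, the default).
#' @param ref,alt Allele labels.
#' @return A locus tibble.
#' @export
locus_spec <- function(chrom, pos, locus_class = "snp",
                       founder_freq = 0.5, susceptible_freq = 0,
                       beta_Delt = 0, beta_Bend = 0, beta_Feni = 0,
                       cnv_copies = NA_integer_, dominance = 0.5,
                       effect = "unknown", gene_id = NA_character_,
                       recomb = 0.5, ref = "A", alt = "T") {
  loci <- tibble::tibble(
    chrom = chrom, pos = pos, locus_class = locus_class,
    ref = ref, alt = alt,
    founder_freq = founder_freq, susceptible_freq = susceptible_freq,
    beta_Delt = beta_Delt, beta_Bend = beta_Bend, beta_Feni = beta_Feni,
    cnv_copies = cnv_copies, dominance = dominance,
    effect = effect, gene_id = gene_id, recomb = recomb
  )
  validate_locus_spec(loci)
  loci
}

validate_locus_spec <- function(loci) {
  if (any(loci$founder_freq < 0 | loci$founder_freq > 1) ||
      any(loci$susceptible_freq < 0 | loci$susceptible_freq > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  betas <- c(loci$beta_Delt, loci$beta_Bend, loci$beta_Feni)
  if (any(!is.finite(betas))) abort("effect sizes must be finite")
  cn <- loci$cnv_copies[loci$locus_class == "cnv_gene"]
  if (any(is.na(cn)) || any(cn < 2)) {
    abort("cnv_gene loci need cnv_copies >= 2")
  }
  invisible(loci)
}

#' Probit tolerance model
#'
#' Individual tolerance is normal on the log10-dose scale: an individual with
#' summed genetic tolerance score `s` survives a dose `d` with probability
#' `Phi((mu0 + s - log10 d) / sigma)`, the probit liability model underlying
#' dose-mortality bioassay analysis. Its LD50 is `10^(mu0 + s)`.
#'
#' @param mu0 Baseline log10 tolerance of a susceptible genotype.
#' @param sigma Residual tolerance standard deviation (log10 dose, > 0).
#' @return A list of class `tolerance_model`.
#' @export
tolerance_model <- function(mu0 = 0, sigma = 0.3) {
  if (!is.finite(sigma) || sigma <= 0) abort("sigma must be > 0")
  structure(list(mu0 = mu0, sigma = sigma), class = "tolerance_model")
}

# population container: two haplotype matrices (individuals x loci, 0/1)
# plus a female indicator
new_population <- function(hap1, hap2, female) {
  structure(list(hap1 = hap1, hap2 = hap2, female = female),
            class = "poolcross_pop")
}

#' @export
print.poolcross_pop <- function(x, ...) {
  cat(sprintf("<poolcross population: %d individuals (%d females), %d loci>\n",
              nrow(x$hap1), sum(x$female), ncol(x$hap1)))
  invisible(x)
}

pop_size <- function(pop) nrow(pop$hap1)

pop_subset <- function(pop, idx) {
  new_population(pop$hap1[idx, , drop = FALSE],
                 pop$hap2[idx, , drop = FALSE],
                 pop$female[idx])
}

pop_females <- function(pop) pop_subset(pop, which(pop$female))
pop_males <- function(pop) pop_subset(pop, which(!pop$female))

#' Genotype dosages and allele frequencies of a population
#'
#' @param pop A population from [simulate_founders()] or descendants.
#' @return `pop_genotypes()`: integer matrix of alt-allele dosages (0/1/2);
#'   `pop_allele_freq()`: per-locus alt allele frequency;
#'   `pop_copy_number()`: per-locus mean diploid gene copy number
#'   (2 for SNPs; `2 + g (k - 1)` averaged over individuals for
#'   amplification loci with `k = cnv_copies`).
#' @export
pop_genotypes <- function(pop) pop$hap1 + pop$hap2

#' @rdname pop_genotypes
#' @export
pop_allele_freq <- function(pop) colMeans(pop_genotypes(pop)) / 2

#' @rdname pop_genotypes
#' @param loci The locus table.
#' @export
pop_copy_number <- function(pop, loci) {
  g <- pop_genotypes(pop)
  k <- ifelse(is.na(loci$cnv_copies), 1L, loci$cnv_copies)
  2 + colMeans(g) * (k - 1)
}

#' Draw a founder population in Hardy-Weinberg proportions
#'
#' Haplotypes are drawn independently per locus at the given frequencies
#' (linkage equilibrium); linkage acts on transmission through
#' [cross_populations()] via the per-locus recombination fractions.
#'
#' @param n Number of diploid individuals.
#' @param loci Locus table ([locus_spec()]).
#' @param freq Which frequency column to use: `"founder_freq"` or
#'   `"susceptible_freq"`.
#' @return A population object.
#' @export
simulate_founders <- function(n, loci, freq = c("founder_freq",
                                                "susceptible_freq")) {
  freq <- match.arg(freq)
  validate_locus_spec(loci)
  if (n <= 0) abort("population size must be positive")
  p <- loci[[freq]]
  L <- nrow(loci)
  hap1 <- matrix(rbinom(n * L, 1L, rep(p, each = n)), nrow = n)
  hap2 <- matrix(rbinom(n * L, 1L, rep(p, each = n)), nrow = n)
  female <- runif(n) < 0.5
  new_population(hap1, hap2, female)
}

# summed liability contribution: g copies contribute beta * (g + (2h-1)[g==1])
# so that het = 2*h*beta and hom = 2*beta; only loci with nonzero effect on
# this insecticide are touched
liability_scores <- function(pop, loci, insecticide) {
  beta <- loci[[paste0("beta_", insecticide)]]
  nz <- which(beta != 0)
  if (length(nz) == 0) return(numeric(pop_size(pop)))
  g <- pop$hap1[, nz, drop = FALSE] + pop$hap2[, nz, drop = FALSE]
  h <- loci$dominance[nz]
  adj <- g + (g == 1L) * rep(2 * h - 1, each = nrow(g))
  as.numeric(adj %*% beta[nz])
}

#' Survival probability under the probit tolerance model
#'
#' @param score Summed genetic tolerance score(s) (log10-dose units).
#' @param dose Insecticide dose (> 0, same units as `10^mu0`).
#' @param model A [tolerance_model()].
#' @return `P(survive) = Phi((mu0 + score - log10 dose) / sigma)`.
#' @export
survival_probability <- function(score, dose, model) {
  if (any(!is.finite(dose) | dose <= 0)) abort("dose must be positive")
  pnorm((model$mu0 + score - log10(dose)) / model$sigma)
}

#' Dose giving a target expected mortality
#'
#' Monotone root-finding on expected population mortality under the probit
#' model; converges to relative dose tolerance 1e-6.
#'
#' @param pop Population to expose.
#' @param loci Locus table.
#' @param model [tolerance_model()].
#' @param insecticide `"Delt"`, `"Bend"` or `"Feni"`.
#' @param mortality Target mortality fraction in (0, 1); e.g. 0.8 for LD80.
#' @return The dose (not its log).
#' @export
find_ld <- function(pop, loci, model, insecticide, mortality) {
  if (mortality <= 0 || mortality >= 1) abort("mortality must be in (0, 1)")
  s <- liability_scores(pop, loci, insecticide)
  f <- function(x) mean(1 - pnorm((model$mu0 + s - x) / model$sigma)) - mortality
  lo <- model$mu0 + min(s) - 10 * model$sigma
  hi <- model$mu0 + max(s) + 10 * model$sigma
  if (f(lo) > 0 || f(hi) < 0) {
    abort("target mortality unattainable within the dose bracket")
  }
  x <- uniroot(f, c(lo, hi), tol = 1e-9)$root
  10^x
}

#' Expose a population and keep the survivors
#'
#' Each individual survives independently with its [survival_probability()].
#'
#' @inheritParams find_ld
#' @param dose Exposure dose (> 0).
#' @return The surviving subpopulation (genotypes retained).
#' @export
select_survivors <- function(pop, loci, model, insecticide, dose) {
  p <- survival_probability(liability_scores(pop, loci, insecticide),
                            dose, model)
  alive <- runif(pop_size(pop)) < p
  if (!any(alive)) {
    abort("no survivors at this dose; increase the census size")
  }
  pop_subset(pop, which(alive))
}

# one gamete per offspring: choose hap1/hap2 per locus with a Markov switch
# process along each chromosome (switch prob = recomb fraction); r = 0.5
# everywhere is independent assortment
draw_gametes <- function(pop, parent_idx, loci) {
  L <- nrow(loci)
  new_chrom <- c(TRUE, loci$chrom[-1] != loci$chrom[-L])
  draw_gametes_cpp(pop$hap1, pop$hap2, as.integer(parent_idx),
                   new_chrom, as.numeric(loci$recomb))
}

#' Mendelian cross between two parent sets
#'
#' Each offspring draws a random mother and father (with replacement) and one
#' recombinant gamete from each.
#'
#' @param mothers,fathers Populations (non-empty).
#' @param n_offspring Number of offspring.
#' @param loci Locus table (provides recombination fractions).
#' @return Offspring population with random sex.
#' @export
cross_populations <- function(mothers, fathers, n_offspring, loci) {
  if (pop_size(mothers) == 0 || pop_size(fathers) == 0) {
    abort("both parent sets must be non-empty")
  }
  mi <- sample.int(pop_size(mothers), n_offspring, replace = TRUE)
  fi <- sample.int(pop_size(fathers), n_offspring, replace = TRUE)
  hap1 <- draw_gametes(mothers, mi, loci)
  hap2 <- draw_gametes(fathers, fi, loci)
  new_population(hap1, hap2, runif(n_offspring) < 0.5)
}

#' Run the full cross / dose-segregation design
#'
#' Executes, for each insecticide line: LD80 exposure of founder females,
#' mass cross of 100 surviving females with 100 susceptible males, free F1
#' mating, F2 production, and segregation of F2 females with the line's LD25
#' and LD75 doses. Returns the 13 sequencing pools (100 females each) with
#' their ground-truth allele frequencies and mean gene copy numbers, the
#' survivor-census frequencies at every stage, and the doses used.
#'
#' F2 females not sampled for the unexposed pool are split 35/65 between the
#' LD25 and LD75 exposures so that both batches leave comfortably more than
#' a pool's worth of expected survivors at the default census.
#'
#' @param loci Locus table ([locus_spec()]).
#' @param model [tolerance_model()].
#' @param n_founders,census Founder population size and per-generation census
#'   (default 2000 each).
#' @param pool_size Individuals per sequencing pool (default 100).
#' @param n_cross Females (and susceptible males) entering the mass cross
#'   (default 100).
#' @return A list of class `cross_design` with elements `pools` (named list
#'   of 13 populations), `truth` (tibble: locus x condition pool frequency
#'   and mean copy number), `census` (tibble: per line, stage and locus, the
#'   frequency over the full cohort at that stage), `doses` and `loci`.
#' @export
run_cross_design <- function(loci, model = tolerance_model(),
                             n_founders = 2000, census = 2000,
                             pool_size = 100, n_cross = 100) {
  validate_locus_spec(loci)
  founders <- simulate_founders(n_founders, loci, "founder_freq")
  susceptible <- simulate_founders(census, loci, "susceptible_freq")
  f0_females <- pop_females(founders)
  if (pop_size(f0_females) < pool_size) {
    abort("founder census leaves fewer females than one pool")
  }

  pools <- list()
  truth <- list()
  census_rows <- list()
  doses <- list()

  take_pool <- function(pop, k) {
    if (pop_size(pop) < k) {
      abort(sprintf("only %d individuals available for a pool of %d",
                    pop_size(pop), k))
    }
    pop_subset(pop, sample.int(pop_size(pop), k))
  }
  record_census <- function(pop, line, stage) {
    tibble::tibble(line = line, stage = stage,
                   chrom = loci$chrom, pos = loci$pos,
                   freq = pop_allele_freq(pop))
  }

  pools[["F0"]] <- take_pool(f0_females, pool_size)
  census_rows[["F0"]] <- record_census(f0_females, "none", "F0")

  for (line in line_levels()) {
    ld80 <- find_ld(f0_females, loci, model, line, 0.8)
    surv80 <- select_survivors(f0_females, loci, model, line, ld80)
    pools[[paste0(line, "_F0_LD80")]] <- take_pool(surv80, pool_size)
    census_rows[[paste0(line, "_F0_LD80")]] <-
      record_census(surv80, line, "F0_LD80")

    mothers <- take_pool(surv80, n_cross)
    fathers <- take_pool(pop_males(susceptible), n_cross)
    f1 <- cross_populations(mothers, fathers, census, loci)
    f2 <- cross_populations(pop_females(f1), pop_males(f1), census, loci)
    f2f <- pop_females(f2)
    census_rows[[paste0(line, "_F2")]] <- record_census(f2f, line, "F2")

    idx <- sample.int(pop_size(f2f))
    unexposed <- pop_subset(f2f, idx[seq_len(pool_size)])
    rest <- idx[-seq_len(pool_size)]
    n25 <- floor(0.35 * length(rest))
    batch25 <- pop_subset(f2f, rest[seq_len(n25)])
    batch75 <- pop_subset(f2f, rest[-seq_len(n25)])
    pools[[paste0(line, "_F2")]] <- unexposed

    ld25 <- find_ld(f2f, loci, model, line, 0.25)
    ld75 <- find_ld(f2f, loci, model, line, 0.75)
    surv25 <- select_survivors(batch25, loci, model, line, ld25)
    surv75 <- select_survivors(batch75, loci, model, line, ld75)
    pools[[paste0(line, "_F2_LD25")]] <- take_pool(surv25, pool_size)
    pools[[paste0(line, "_F2_LD75")]] <- take_pool(surv75, pool_size)
    census_rows[[paste0(line, "_F2_LD25")]] <-
      record_census(surv25, line, "F2_LD25")
    census_rows[[paste0(line, "_F2_LD75")]] <-
      record_census(surv75, line, "F2_LD75")
    doses[[line]] <- tibble::tibble(line = line, ld80 = ld80,
                                    ld25 = ld25, ld75 = ld75)
  }

  for (cond in names(pools)) {
    truth[[cond]] <- tibble::tibble(
      condition = cond, chrom = loci$chrom, pos = loci$pos,
      locus_class = loci$locus_class, gene_id = loci$gene_id,
      freq = pop_allele_freq(pools[[cond]]),
      copy_number = pop_copy_number(pools[[cond]], loci)
    )
  }

  structure(list(
    pools = pools[condition_levels()],
    truth = dplyr::bind_rows(truth) %>%
      dplyr::arrange(.data$chrom, .data$pos, .data$condition),
    census = dplyr::bind_rows(census_rows),
    doses = dplyr::bind_rows(doses),
    loci = loci
  ), class = "cross_design")
}
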