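#' Configuration for a synthetic CSRA cohort
#'
#' Defines the generative model for a cohort with known ground truth. The
#' defaults emulate the study conditions the package targets: 25 UPS + 12
#' SS primary cultures, ~27% apoptosis-panel mutation prevalence, a
#' doxorubicin resistance baseline of 14/27 among Mut- specimens with the
#' mutation multiplying the resistance odds by ~8.4, and per-drug
#' mutation-independent resistance rates for the remaining drugs matching
#' the observed cohort fractions. Dose response follows a Hill curve per
#' phenotype: sensitive cultures reach full inhibition with a half-maximal
#' dose well below 100% TDC; resistant cultures plateau at 40% inhibition.
#'
#' @param n_ups,n_ss Cohort sizes per histotype.
#' @param mut_prevalence Probability a specimen carries a panel mutation.
#' @param odds_ratio Multiplier on the resistance odds for Mut+ specimens
#'   (applies to `or_drug`).
#' @param baseline_resistance_prob Resistance probability for Mut-
#'   specimens on `or_drug`.
#' @param or_drug Drug carrying the planted mutation effect.
#' @param drug_resistance_probs Named resistance probabilities for the
#'   other drugs (mutation-independent).
#' @param hill_sensitive,hill_resistant Hill parameters per phenotype:
#'   list with `imax` (plateau, percent inhibition), `ec50` (half-maximal
#'   dose in percent-of-TDC units) and `h` (slope).
#' @param vehicle_mean,blank_mean Mean control signals (arbitrary
#'   fluorescence units).
#' @param noise_sd Additive Gaussian noise SD on every well signal
#'   (signals are truncated at 0; plate readers report non-negative
#'   values).
#' @param replicates Treated/control replicates per condition.
#' @param panel_genes Genes from which a Mut+ specimen's mutated gene is
#'   drawn.
#' @param seed Integer seed; identical configs and seeds give identical
#'   cohorts.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(
    n_ups = 25L, n_ss = 12L,
    mut_prevalence = 10 / 37,
    odds_ratio = (9 / 1) / (14 / 13),
    baseline_resistance_prob = 14 / 27,
    or_drug = "Dox",
    drug_resistance_probs = c("Ifo" = 0.64, "Dox+Ifo" = 0.43,
                              "Doc" = 0.68, "Gem" = 0.61,
                              "Doc+Gem" = 0.45),
    hill_sensitive = list(imax = 100, ec50 = 12.5, h = 2),
    hill_resistant = list(imax = 40, ec50 = 100, h = 1.5),
    vehicle_mean = 10000, blank_mean = 500, noise_sd = 150,
    replicates = 3L, panel_genes = c("TP53", "ATM", "PIK3CB", "PIK3R1",
                                     "NTRK1", "CSF2RB"),
    seed = 1L) {
  cfg <- list(n_ups = as.integer(n_ups), n_ss = as.integer(n_ss),
              mut_prevalence = mut_prevalence, odds_ratio = odds_ratio,
              baseline_resistance_prob = baseline_resistance_prob,
              or_drug = or_drug,
              drug_resistance_probs = drug_resistance_probs,
              hill_sensitive = hill_sensitive,
              hill_resistant = hill_resistant,
              vehicle_mean = vehicle_mean, blank_mean = blank_mean,
              noise_sd = noise_sd, replicates = as.integer(replicates),
              panel_genes = toupper(panel_genes), seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_cohort_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$mut_prevalence, cfg$baseline_resistance_prob,
             cfg$drug_resistance_probs)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$odds_ratio <= 0)
    stop("config error: odds_ratio must be positive", call. = FALSE)
  for (h in list(cfg$hill_sensitive, cfg$hill_resistant))
    if (h$ec50 <= 0 || h$h <= 0 || h$imax < 0 || h$imax > 100)
      stop("config error: need ec50 > 0, h > 0, imax in [0, 100]",
           call. = FALSE)
  if (cfg$vehicle_mean <= cfg$blank_mean)
    stop("config error: vehicle_mean must exceed blank_mean",
         call. = FALSE)
  if (cfg$n_ups + cfg$n_ss < 1L || cfg$replicates < 1L)
    stop("config error: empty cohort or no replicates", call. = FALSE)
  invisible(cfg)
}

#' Hill-curve percent inhibition
#'
#' inhibition(c) = Imax c^h / (ec50^h + c^h); monotone increasing in the
#' dose c for h > 0.
#'
#' @param conc Dose (percent-of-TDC units), vectorised.
#' @param imax Plateau inhibition (percent).
#' @param ec50 Half-maximal dose.
#' @param h Hill slope.
#' @return Percent inhibition.
#' @export
hill_inhibition <- function(conc, imax, ec50, h) {
  imax * conc^h / (ec50^h + conc^h)
}

# Resistance probability for Mut+ given Mut- baseline p0 and odds ratio.
or_to_prob <- function(p0, odds_ratio) {
  odds <- odds_ratio * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Sample cohort-level ground truth
#'
#' Draws histotype labels, mutation status (Bernoulli at the configured
#' prevalence), a mutated panel gene per Mut+ specimen, and a
#' sensitive/resistant phenotype per drug: on the effect-carrying drug the
#' Mut+ resistance odds are the Mut- odds times the configured odds ratio;
#' other drugs use their mutation-independent rates. Also records the
#' noiseless target SI implied by each phenotype's Hill curve.
#'
#' @param config A [synthetic_cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return data.frame: `specimen_id`, `histotype`, `mut_status`,
#'   `mut_gene`, then one `phenotype_<drug>` column per drug, plus
#'   `target_si_sensitive`, `target_si_resistant`.
#' @export
sample_ground_truth <- function(config, seed = NULL) {
  validate_config(config)
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_ups + config$n_ss
  ids <- sprintf("SYN%03d", seq_len(n))
  hist <- c(rep("UPS", config$n_ups), rep("SS", config$n_ss))
  mut <- stats::runif(n) < config$mut_prevalence
  gene <- ifelse(mut, sample(config$panel_genes, n, replace = TRUE),
                 NA_character_)
  p1 <- or_to_prob(config$baseline_resistance_prob, config$odds_ratio)
  drugs <- c(config$or_drug, names(config$drug_resistance_probs))
  truth <- data.frame(specimen_id = ids, histotype = hist,
                      mut_status = mut, mut_gene = gene,
                      stringsAsFactors = FALSE)
  for (d in drugs) {
    pr <- if (d == config$or_drug) {
      ifelse(mut, p1, config$baseline_resistance_prob)
    } else {
      rep(config$drug_resistance_probs[[d]], n)
    }
    truth[[paste0("phenotype_", d)]] <-
      ifelse(stats::runif(n) < pr, "resistant", "sensitive")
  }
  hs <- config$hill_sensitive; hr <- config$hill_resistant
  truth$target_si_sensitive <-
    600 - sum(hill_inhibition(TDC_LADDER, hs$imax, hs$ec50, hs$h))
  truth$target_si_resistant <-
    600 - sum(hill_inhibition(TDC_LADDER, hr$imax, hr$ec50, hr$h))
  truth
}

#' Generate a full synthetic cohort
#'
#' Samples ground truth and, from it, plate-reader well signals
#' (treated wells follow the phenotype's Hill curve, with additive
#' Gaussian noise truncated at zero), a planted variant table (one random
#' panel-gene missense or nonsense variant per Mut+ specimen) and the
#' specimen annotation table. The whole cohort is a deterministic function
#' of (config, seed).
#'
#' @param config A [synthetic_cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @param plates Generate well-level plate data (default TRUE; set FALSE
#'   for fast truth-level simulation).
#' @return List of class `synthetic_cohort`: `truth`, `wells` (long-form
#'   plate table as in [read_plate_csv()]), `variants`, `annotations`,
#'   `config`.
#' @export
gen_cohort <- function(config = synthetic_cohort_config(), seed = NULL,
                       plates = TRUE) {
  truth <- sample_ground_truth(config, seed = seed)
  n <- nrow(truth)
  drugs <- c(config$or_drug, names(config$drug_resistance_probs))

  annotations <- truth[, c("specimen_id", "histotype")]

  mutated <- truth[truth$mut_status, , drop = FALSE]
  variants <- if (nrow(mutated)) {
    cons <- sample(c("missense", "nonsense"), nrow(mutated),
                   replace = TRUE)
    pos <- sample.int(1e6L, nrow(mutated))
    data.frame(
      specimen_id = mutated$specimen_id,
      gene = mutated$mut_gene,
      genomic_change = sprintf("g.chr1:%d%s>%s", pos,
                               sample(c("A", "C", "G", "T"),
                                      nrow(mutated), replace = TRUE),
                               sample(c("A", "C", "G", "T"),
                                      nrow(mutated), replace = TRUE)),
      protein_change = ifelse(cons == "nonsense",
                              sprintf("p.Q%d*", 1 + pos %% 300),
                              sprintf("p.A%dV", 1 + pos %% 300)),
      consequence = cons,
      cosmic_id = "",
      lof_class = "unknown",
      stringsAsFactors = FALSE)
  } else {
    empty_variants()
  }

  wells <- NULL
  if (plates) {
    hill <- list(sensitive = config$hill_sensitive,
                 resistant = config$hill_resistant)
    span <- config$vehicle_mean - config$blank_mean
    rep_n <- config$replicates
    blocks <- vector("list", n * length(drugs))
    bi <- 0L
    for (i in seq_len(n)) {
      for (d in drugs) {
        ph <- truth[[paste0("phenotype_", d)]][i]
        hp <- hill[[ph]]
        inh <- hill_inhibition(TDC_LADDER, hp$imax, hp$ec50, hp$h)
        mu_treat <- config$blank_mean + span * (1 - inh / 100)
        sig <- c(rep(mu_treat, each = rep_n),
                 rep(config$vehicle_mean, rep_n),
                 rep(config$blank_mean, rep_n))
        if (config$noise_sd > 0)
          sig <- sig + stats::rnorm(length(sig), 0, config$noise_sd)
        sig <- pmax(sig, 0)
        bi <- bi + 1L
        blocks[[bi]] <- data.frame(
          specimen_id = truth$specimen_id[i], drug = d,
          well_role = c(rep("treated", 6L * rep_n),
                        rep("vehicle", rep_n), rep("blank", rep_n)),
          tdc_fraction = c(rep(TDC_LADDER, each = rep_n),
                           rep(NA_real_, 2L * rep_n)),
          replicate = c(rep(seq_len(rep_n), times = 6L),
                        seq_len(rep_n), seq_len(rep_n)),
          signal = sig, stringsAsFactors = FALSE)
      }
    }
    wells <- do.call(rbind, blocks)
    rownames(wells) <- NULL
  }

  structure(list(truth = truth, wells = wells, variants = variants,
                 annotations = annotations, config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes `plates.csv`, `variants.tsv`, `annotations.tsv`, `truth.tsv` and
#' `config.dcf` into a directory, in the same dialects the scoring and
#' panel readers accept.
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$wells))
    utils::write.csv(cohort$wells, file.path(dir, "plates.csv"),
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotations,
                     file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  flat <- lapply(cfg, function(x)
    if (is.list(x)) paste(unlist(x), collapse = ",")
    else paste(x, collapse = ","))
  write.dcf(as.data.frame(flat, check.names = FALSE),
            file.path(dir, "config.dcf"))
  invisible(dir)
}
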