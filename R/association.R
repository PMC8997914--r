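#' Hypergeometric probability mass
#'
#' P(X = k) for X hypergeometric with population size N, K successes in the
#' population and n draws: C(K, k) C(N - K, n - k) / C(N, n), evaluated in
#' log space via `lchoose` for numerical stability at large margins.
#' Out-of-support k returns 0 (not an error); invalid margins are a domain
#' error. This kernel underlies the one-sided Fisher exact test.
#'
#' @param k Number of successes drawn (vectorised).
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Draws.
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' hypergeom_pmf(3, N = 12, K = 6, n = 3)  # 20/220
hypergeom_pmf <- function(k, N, K, n) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L ||
      N < 0 || K < 0 || K > N || n < 0 || n > N ||
      any(c(N, K, n) != floor(c(N, K, n))))
    stop("domain error: need integers 0 <= K <= N, 0 <= n <= N",
         call. = FALSE)
  ok <- k >= max(0, n + K - N) & k <= min(n, K) & k == floor(k)
  p <- numeric(length(k))
  ki <- k[ok]
  p[ok] <- exp(lchoose(K, ki) + lchoose(N - K, n - ki) - lchoose(N, n))
  p
}

#' Build a 2x2 contingency table of mutation status vs call
#'
#' Layout: rows \{Mut+, Mut-\}, columns \{sensitive, resistant\}.
#'
#' @param a Mut+ sensitive count.
#' @param b Mut+ resistant count.
#' @param c Mut- sensitive count.
#' @param d Mut- resistant count.
#' @return A `contingency_2x2` integer matrix.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("domain error: cell counts must be non-negative integers",
         call. = FALSE)
  m <- matrix(as.integer(cells), nrow = 2, byrow = TRUE,
              dimnames = list(c("Mut+", "Mut-"),
                              c("sensitive", "resistant")))
  structure(m, class = c("contingency_2x2", class(m)))
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Tests association between panel mutation status (rows) and the
#' resistance call (columns). Under the null, the resistant count X among
#' the Mut+ specimens is hypergeometric with fixed margins
#' (N = table total, K = total resistant, n = Mut+ total). The upper tail
#' is P(X >= observed) — enrichment of resistance among Mut+ — and the
#' lower tail is P(X <= observed). `tail = "auto"` reports the smaller of
#' the two, labelled with its direction; fixed `"upper"`/`"lower"` are
#' available. A zero Mut+ or Mut- margin is degenerate: p = 1 with a flag.
#'
#' @param table A `contingency_2x2` (or any 2x2 matrix in the same layout).
#' @param tail `"auto"` (default), `"upper"` or `"lower"`.
#' @return List of class `fisher_result`: `p` (in (0, 1\]), `tail` (the
#'   tail actually reported), `observed` (resistant among Mut+), `table`,
#'   `degenerate` (logical), `n` (table total).
#' @export
#' @examples
#' fisher_one_sided(contingency_2x2(1, 9, 13, 14))$p  # 0.036
fisher_one_sided <- function(table, tail = c("auto", "upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  N <- sum(table)
  K <- sum(table[, 2L])          # total resistant
  n <- sum(table[1L, ])          # Mut+ total
  x <- table[1L, 2L]             # resistant among Mut+
  if (N < 1L)
    stop("domain error: empty table", call. = FALSE)
  degenerate <- n == 0L || n == N
  if (degenerate) {
    return(structure(list(p = 1, tail = tail, observed = x,
                          table = table, degenerate = TRUE, n = N),
                     class = "fisher_result"))
  }
  support <- max(0L, n + K - N):min(n, K)
  pmf <- hypergeom_pmf(support, N, K, n)
  upper <- sum(pmf[support >= x])
  lower <- sum(pmf[support <= x])
  p <- switch(tail,
              upper = upper,
              lower = lower,
              auto = min(upper, lower))
  used <- switch(tail,
                 upper = "upper", lower = "lower",
                 auto = if (upper <= lower) "upper" else "lower")
  structure(list(p = min(p, 1), tail = used, observed = x, table = table,
                 degenerate = FALSE, n = N),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("one-sided Fisher exact (%s tail): p = %.4g%s\n",
              x$tail, x$p,
              if (x$degenerate) " [degenerate margin]" else ""))
  invisible(x)
}

#' Stratified mutation-resistance association grid
#'
#' For each drug and each stratum (UPS, SS and the pooled STS cohort)
#' builds the 2x2 table of mutation status against the sensitive/resistant
#' call and computes the one-sided Fisher exact p-value (auto tail by
#' default). Specimens lacking a call for a drug are excluded pairwise
#' from that drug's tables; a stratum with no evaluable specimens is
#' flagged NA.
#'
#' @param matrix Mutation matrix from [build_mutation_matrix()], or a named
#'   logical Mut+ status vector.
#' @param calls data.frame with `specimen_id`, `drug`, `call`
#'   (sensitive/resistant; NA allowed) — e.g. [score_plates()] output.
#' @param annotations data.frame with `specimen_id`, `histotype`.
#' @param drugs Drugs to test (default: all in `calls`).
#' @param tail Passed to [fisher_one_sided()].
#' @param bh_adjust Add a Benjamini-Hochberg adjusted-p column (off by
#'   default; the headline analysis applies no multiplicity correction).
#' @return data.frame of class `association_grid`: one row per drug x
#'   stratum with counts `mut_sensitive`, `mut_resistant`,
#'   `nomut_sensitive`, `nomut_resistant`, `p`, `tail`, `n_evaluable`,
#'   `degenerate`.
#' @export
stratified_association <- function(matrix, calls, annotations,
                                   drugs = NULL,
                                   tail = c("auto", "upper", "lower"),
                                   bh_adjust = FALSE) {
  tail <- match.arg(tail)
  status <- if (is.matrix(matrix)) mutation_status(matrix) else matrix
  if (is.null(drugs)) drugs <- unique(calls$drug)
  strata <- list(UPS = "UPS", SS = "SS", STS = c("UPS", "SS"))
  rows <- list()
  for (drug in drugs) {
    dc <- calls[calls$drug == drug & !is.na(calls$call), , drop = FALSE]
    for (sname in names(strata)) {
      sids <- annotations$specimen_id[
        annotations$histotype %in% strata[[sname]]]
      sub <- dc[dc$specimen_id %in% sids, , drop = FALSE]
      if (nrow(sub) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          drug = drug, stratum = sname,
          mut_sensitive = NA_integer_, mut_resistant = NA_integer_,
          nomut_sensitive = NA_integer_, nomut_resistant = NA_integer_,
          p = NA_real_, tail = NA_character_, n_evaluable = 0L,
          degenerate = NA, stringsAsFactors = FALSE)
        next
      }
      mut <- status[sub$specimen_id]
      sens <- sub$call == "sensitive"
      tab <- contingency_2x2(sum(mut & sens), sum(mut & !sens),
                             sum(!mut & sens), sum(!mut & !sens))
      fr <- fisher_one_sided(tab, tail = tail)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug, stratum = sname,
        mut_sensitive = tab[1, 1], mut_resistant = tab[1, 2],
        nomut_sensitive = tab[2, 1], nomut_resistant = tab[2, 2],
        p = fr$p, tail = fr$tail, n_evaluable = fr$n,
        degenerate = fr$degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh_adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("association_grid", class(out))
  out
}

#' Partial loss-of-function reassignment analysis
#'
#' Specimens whose only qualifying panel variants are annotated as partial
#' loss of function (`lof_class = "partial"`) arguably retain pathway
#' activity. This analysis either moves them to the Mut- group
#' (`policy = "reassign"`, default) or drops them (`policy = "exclude"`)
#' and recomputes the association for one drug. With no partial-LOF
#' specimens the baseline result is returned, flagged unchanged.
#'
#' @param variants Variant data.frame with `lof_class` populated (see
#'   [apply_lof_overrides()]).
#' @param panel Gene panel.
#' @param cohort_specimens Full specimen list.
#' @param calls Calls data.frame (as in [stratified_association()]).
#' @param annotations Specimen annotation data.frame.
#' @param drug Drug to recompute (default `"Dox"`).
#' @param policy `"reassign"` or `"exclude"`.
#' @param tail Passed to [fisher_one_sided()].
#' @return List: `p`, `tail`, `table`, `policy`, `reassigned` (specimen
#'   IDs moved/dropped), `baseline_p`, `changed` (logical).
#' @export
reassignment_analysis <- function(variants, panel, cohort_specimens,
                                  calls, annotations, drug = "Dox",
                                  policy = c("reassign", "exclude"),
                                  tail = "auto") {
  policy <- match.arg(policy)
  m <- build_mutation_matrix(variants, panel, cohort_specimens)
  status <- mutation_status(m)
  base <- stratified_association(m, calls, annotations, drugs = drug,
                                 tail = tail)
  baseline_p <- base$p[base$stratum == "STS"]

  if (!inherits(panel, "gene_panel")) panel <- load_panel(panel)
  q <- variants[variants$consequence %in% QUALIFYING_CONSEQUENCES &
                  variants$gene %in% panel$genes, , drop = FALSE]
  only_partial <- vapply(names(status)[status], function(s) {
    cls <- q$lof_class[q$specimen_id == s]
    length(cls) > 0L && all(cls == "partial")
  }, logical(1))
  moved <- names(status)[status][only_partial]

  if (!length(moved)) {
    return(list(p = baseline_p, tail = base$tail[base$stratum == "STS"],
                table = NULL, policy = policy, reassigned = character(),
                baseline_p = baseline_p, changed = FALSE))
  }
  status2 <- status
  ann2 <- annotations
  if (policy == "reassign") {
    status2[moved] <- FALSE
  } else {
    status2 <- status2[setdiff(names(status2), moved)]
    ann2 <- ann2[!ann2$specimen_id %in% moved, , drop = FALSE]
  }
  res <- stratified_association(status2, calls, ann2, drugs = drug,
                                tail = tail)
  sts <- res[res$stratum == "STS", ]
  list(p = sts$p, tail = sts$tail,
       table = contingency_2x2(sts$mut_sensitive, sts$mut_resistant,
                               sts$nomut_sensitive, sts$nomut_resistant),
       policy = policy, reassigned = moved, baseline_p = baseline_p,
       changed = TRUE)
}

#' Histotype distribution of TP53 vs other-gene mutations
#'
#' Among mutated (Mut+) specimens, tests whether carrying a TP53 mutation
#' (vs alterations only in other panel genes) is distributed differently
#' between the two histotypes: 2x2 with rows \{UPS, SS\} and columns
#' \{TP53-mutated, other-gene-only\}, one-sided Fisher exact (auto tail).
#'
#' @param variants Variant data.frame (qualifying consequences only are
#'   counted).
#' @param panel Gene panel.
#' @param cohort_specimens Full specimen list.
#' @param annotations Specimen annotation data.frame.
#' @param gene Focal gene (default `"TP53"`).
#' @return A `fisher_result` with the table (rows UPS/SS, columns
#'   focal-gene/other-only), or NA-flagged list when a histotype has no
#'   mutated specimens.
#' @export
gene_class_distribution_test <- function(variants, panel,
                                         cohort_specimens, annotations,
                                         gene = "TP53") {
  m <- build_mutation_matrix(variants, panel, cohort_specimens)
  status <- mutation_status(m)
  mut_ids <- names(status)[status]
  if (!length(mut_ids)) return(list(p = NA_real_, degenerate = TRUE))
  has_focal <- if (gene %in% colnames(m)) m[mut_ids, gene] > 0L
    else rep(FALSE, length(mut_ids))
  hist <- annotations$histotype[match(mut_ids, annotations$specimen_id)]
  if (length(unique(hist)) < 2L) return(list(p = NA_real_, degenerate = TRUE))
  tab <- matrix(c(sum(hist == "UPS" & has_focal),
                  sum(hist == "UPS" & !has_focal),
                  sum(hist == "SS" & has_focal),
                  sum(hist == "SS" & !has_focal)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("UPS", "SS"),
                                c(gene, "other-only")))
  fisher_one_sided(tab, tail = "auto")
}

#' Write an association grid as a TSV and JSON pair
#'
#' The TSV is the drug x stratum grid of counts and p-values; the JSON
#' carries one record per cell with full precision.
#'
#' @param grid [stratified_association()] output.
#' @param tsv_path,json_path Destinations (either may be NULL to skip).
#' @return The grid, invisibly.
#' @export
write_association <- function(grid, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(grid, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(grid, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(grid)
}
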