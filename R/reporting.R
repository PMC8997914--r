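#' Bin sensitivity indices into a histogram table
#'
#' Bins SI values into right-open bins over \[0, 600\] (the last bin is
#' closed so SI = 600 is kept), split by histotype and drug and labelled
#' with the sensitivity side: bins entirely below 250 are sensitive, bins
#' at or above 250 resistant. The default width of 50 makes the 250
#' threshold a bin boundary. Counts conserve n: every SI lands in exactly
#' one bin.
#'
#' @param si_table [score_plates()] output (needs `specimen_id`, `drug`,
#'   `si`).
#' @param annotations Specimen annotation data.frame (`specimen_id`,
#'   `histotype`).
#' @param bin_width Bin width in SI units (default 50).
#' @return data.frame: `drug`, `histotype`, `bin_lo`, `bin_hi`, `side`,
#'   `count`. Strata include the pooled `"STS"` row.
#' @export
si_histogram <- function(si_table, annotations, bin_width = 50) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("config error: bin_width must be a positive number",
         call. = FALSE)
  if (nrow(si_table) == 0L)
    stop("config error: empty SI table", call. = FALSE)
  breaks <- unique(c(seq(0, 600, by = bin_width), 600))
  si_table$histotype <- annotations$histotype[
    match(si_table$specimen_id, annotations$specimen_id)]
  strata <- list(UPS = "UPS", SS = "SS", STS = c("UPS", "SS"))
  out <- list()
  for (drug in unique(si_table$drug)) {
    for (sname in names(strata)) {
      x <- si_table$si[si_table$drug == drug &
                         si_table$histotype %in% strata[[sname]]]
      x <- x[is.finite(x)]
      cuts <- cut(x, breaks = breaks, right = FALSE,
                  include.lowest = TRUE)
      cnt <- table(cuts)
      lo <- breaks[-length(breaks)]
      hi <- breaks[-1]
      out[[length(out) + 1L]] <- data.frame(
        drug = drug, histotype = sname, bin_lo = lo, bin_hi = hi,
        side = ifelse(hi <= SI_THRESHOLD, "sensitive", "resistant"),
        count = as.integer(cnt), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-drug resistance fractions
#'
#' @param calls Calls data.frame (`specimen_id`, `drug`, `call`; NA calls
#'   are excluded pairwise).
#' @return data.frame: `drug`, `n_evaluable`, `n_resistant`,
#'   `resistant_fraction`.
#' @export
resistance_fractions <- function(calls) {
  cc <- calls[!is.na(calls$call), , drop = FALSE]
  out <- do.call(rbind, lapply(split(cc, cc$drug), function(d) {
    data.frame(drug = d$drug[1], n_evaluable = nrow(d),
               n_resistant = sum(d$call == "resistant"),
               resistant_fraction = mean(d$call == "resistant"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Oncoplot-style co-occurrence table
#'
#' One row per specimen: histotype, the 0/1 panel-gene mutation columns,
#' then one call column per drug coded R (resistant), S (sensitive) or NA
#' (no call). Rows are sorted by histotype (UPS first), Mut+ specimens
#' before Mut- within a histotype.
#'
#' @param matrix Mutation matrix from [build_mutation_matrix()].
#' @param calls Calls data.frame.
#' @param annotations Specimen annotation data.frame.
#' @return data.frame in oncoplot layout.
#' @export
oncoplot_matrix <- function(matrix, calls, annotations) {
  specs <- rownames(matrix)
  if (!length(intersect(specs, annotations$specimen_id)) ||
      !length(intersect(specs, calls$specimen_id)))
    stop("join error: matrix, calls and annotations share no specimens",
         call. = FALSE)
  df <- data.frame(specimen_id = specs,
                   histotype = annotations$histotype[
                     match(specs, annotations$specimen_id)],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(unclass(matrix))[specs, , drop = FALSE])
  for (drug in unique(calls$drug)) {
    dc <- calls[calls$drug == drug, ]
    cl <- dc$call[match(specs, dc$specimen_id)]
    df[[drug]] <- ifelse(is.na(cl), NA_character_,
                         ifelse(cl == "resistant", "R", "S"))
  }
  mut <- mutation_status(matrix)[specs]
  ord <- order(factor(df$histotype, levels = c("UPS", "SS")),
               !mut, df$specimen_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read the oncoplot table (TSV round trip)
#'
#' @param oncoplot [oncoplot_matrix()] output.
#' @param path TSV destination.
#' @return `path`, invisibly.
#' @export
write_oncoplot_tsv <- function(oncoplot, path) {
  utils::write.table(oncoplot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_oncoplot_tsv
#' @export
read_oncoplot_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA")
}

#' Full cohort report
#'
#' Orchestrates the reporting stage: resistance fractions, SI histograms
#' (when SI values are available), the oncoplot table and the stratified
#' association grid; optionally writes all four as TSV into a directory.
#'
#' @param si_table [score_plates()] output, or a calls data.frame
#'   (`specimen_id`, `drug`, `call`) when raw SI values are unavailable.
#' @param matrix Mutation matrix.
#' @param annotations Specimen annotation data.frame.
#' @param out_dir Optional output directory.
#' @return List of class `cohort_report`: `resistance`, `histogram` (NULL
#'   without SI values), `oncoplot`, `association`.
#' @export
cohort_report <- function(si_table, matrix, annotations, out_dir = NULL) {
  has_si <- "si" %in% names(si_table)
  calls <- si_table[, intersect(c("specimen_id", "drug", "call"),
                                names(si_table))]
  rep <- list(
    resistance = resistance_fractions(calls),
    histogram = if (has_si) si_histogram(si_table, annotations) else NULL,
    oncoplot = oncoplot_matrix(matrix, calls, annotations),
    association = stratified_association(matrix, calls, annotations)
  )
  class(rep) <- "cohort_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA")
    w(rep$resistance, "resistance_fractions.tsv")
    w(rep$histogram, "si_histogram.tsv")
    w(rep$oncoplot, "oncoplot.tsv")
    w(as.data.frame(rep$association), "association_grid.tsv")
  }
  rep
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report\n-- resistance fractions --\n")
  print(x$resistance)
  cat("-- association grid --\n")
  print(as.data.frame(x$association))
  invisible(x)
}
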