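# The six-step drug ladder, as percent of the 100% test drug concentration
# (TDC). Every plate must carry exactly these fractions.
TDC_LADDER <- c(6.25, 12.5, 25, 50, 100, 200)

# SI threshold: SI < 250 is sensitive, SI >= 250 resistant (ties go to
# resistant, the conservative direction).
SI_THRESHOLD <- 250

#' Drug specifications with their 100% test drug concentrations
#'
#' Returns the default drug panel used in the chemosensitivity/
#' chemoresistance assay (CSRA): Doxorubicin, Ifosfamide (as its activated
#' 4-hydroperoxy metabolite), Docetaxel, Gemcitabine, and the two standard
#' clinical combinations. The 100% TDC is the pharmacokinetically chosen
#' reference dose; wells receive 6.25--200% of it. Units are carried as an
#' opaque string and never converted.
#'
#' @return A data.frame with columns `drug`, `tdc_100` (numeric reference
#'   concentration; for combinations, the summed label is in `tdc_label`),
#'   `unit`, `is_combination`, `components` (comma-separated component
#'   names), `tdc_label` (the printed concentration string).
#' @export
#' @examples
#' default_drugs()
default_drugs <- function() {
  data.frame(
    drug = c("Dox", "Ifo", "Dox+Ifo", "Doc", "Gem", "Doc+Gem"),
    tdc_100 = c(1.0, 3.0, 4.0, 11.3, 25.0, 36.3),
    unit = "mg/mL",
    is_combination = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    components = c("Dox", "Ifo", "Dox,Ifo", "Doc", "Gem", "Doc,Gem"),
    tdc_label = c("1.0", "3.0", "1.0 + 3.0", "11.3", "25.0", "11.3 + 25.0"),
    stringsAsFactors = FALSE
  )
}

#' Construct a dose plate for one specimen and drug
#'
#' A `dose_plate` bundles the raw well signals for a single specimen x drug
#' CSRA run: treated wells at the six TDC fractions, vehicle-control wells
#' (untreated cells) and blank wells (medium only).
#'
#' @param specimen_id Specimen identifier.
#' @param drug Drug name (matched against the drug config at scoring time).
#' @param treated Named list: one numeric vector of replicate signals per
#'   TDC fraction; names must be the six ladder fractions
#'   (6.25, 12.5, 25, 50, 100, 200).
#' @param vehicle Numeric vector of vehicle-control signals (length >= 3
#'   recommended; >= 1 required).
#' @param blank Numeric vector of blank signals (length >= 1).
#' @return An object of class `dose_plate`.
#' @export
dose_plate <- function(specimen_id, drug, treated, vehicle, blank) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L,
            is.character(drug), length(drug) == 1L)
  fr <- suppressWarnings(as.numeric(names(treated)))
  if (length(treated) != 6L || anyNA(fr) ||
      !setequal(round(fr, 4), TDC_LADDER)) {
    stop("incomplete-ladder: treated signals must cover exactly the six ",
         "TDC fractions ", paste(TDC_LADDER, collapse = ", "), "%",
         call. = FALSE)
  }
  treated <- treated[order(fr)]
  if (any(vapply(treated, length, 1L) < 1L))
    stop("incomplete-ladder: every fraction needs >= 1 treated replicate",
         call. = FALSE)
  if (length(vehicle) < 1L || length(blank) < 1L)
    stop("dose_plate needs vehicle and blank signals", call. = FALSE)
  structure(
    list(specimen_id = specimen_id, drug = drug,
         treated = lapply(treated, as.numeric),
         vehicle = as.numeric(vehicle), blank = as.numeric(blank)),
    class = "dose_plate"
  )
}

#' Percent inhibition per ladder fraction
#'
#' Normalises treated-well signals against the plate's vehicle (0%
#' inhibition) and blank (100% inhibition) controls:
#' \deqn{I(c) = 100 \left(1 - \frac{\bar{T}_c - \bar{B}}{\bar{V} - \bar{B}}\right)}
#' where \eqn{\bar{T}_c} is the mean treated signal at fraction c,
#' \eqn{\bar{V}} the mean vehicle signal and \eqn{\bar{B}} the mean blank.
#' Replicates are aggregated by arithmetic mean. Both the raw value and a
#' \[0, 100\]-clamped value are returned; the raw value is kept for audit
#' (growth stimulation or super-kill show up as out-of-range raw values).
#'
#' @param plate A [dose_plate()].
#' @return An `inhibition_profile`: list with `specimen_id`, `drug`,
#'   `fractions`, `inhibition_raw`, `inhibition` (clamped), `vehicle_mean`,
#'   `blank_mean`.
#' @export
compute_inhibition <- function(plate) {
  stopifnot(inherits(plate, "dose_plate"))
  v <- mean(plate$vehicle)
  b <- mean(plate$blank)
  if (!is.finite(v) || !is.finite(b) || v <= b)
    stop("degenerate-control: mean vehicle signal (", signif(v, 4),
         ") must exceed mean blank (", signif(b, 4), ")", call. = FALSE)
  tm <- vapply(plate$treated, mean, numeric(1))
  raw <- 100 * (1 - (tm - b) / (v - b))
  structure(
    list(specimen_id = plate$specimen_id, drug = plate$drug,
         fractions = TDC_LADDER,
         inhibition_raw = unname(raw),
         inhibition = pmin(pmax(unname(raw), 0), 100),
         vehicle_mean = v, blank_mean = b),
    class = "inhibition_profile"
  )
}

#' Sensitivity index from an inhibition profile
#'
#' The sensitivity index is SI = 600 minus the sum of percent inhibition at
#' the 200, 100, 50, 25, 12.5 and 6.25% TDC fractions. Lower SI means more
#' sensitive cells. With clamped per-fraction inhibition SI lies in
#' \[0, 600\]; the raw (unclamped) SI is reported alongside. The call is
#' sensitive when SI < 250, resistant when SI >= 250.
#'
#' @param profile An `inhibition_profile` from [compute_inhibition()], or a
#'   bare numeric vector of six percent-inhibition values.
#' @param use_clamped Sum the clamped inhibitions (default TRUE). The raw
#'   sum is reported in `si_raw` regardless.
#' @return A one-row data.frame: `specimen_id`, `drug`, `si`, `si_raw`,
#'   `si_clamped`, `call`.
#' @export
compute_si <- function(profile, use_clamped = TRUE) {
  if (is.numeric(profile)) {
    profile <- list(specimen_id = NA_character_, drug = NA_character_,
                    inhibition_raw = profile,
                    inhibition = pmin(pmax(profile, 0), 100))
  }
  if (length(profile$inhibition) != 6L)
    stop("incomplete-ladder: SI needs exactly 6 inhibition values",
         call. = FALSE)
  si_raw <- 600 - sum(profile$inhibition_raw)
  si_clamped <- 600 - sum(profile$inhibition)
  si <- if (use_clamped) si_clamped else si_raw
  data.frame(
    specimen_id = profile$specimen_id, drug = profile$drug,
    si = si, si_raw = si_raw, si_clamped = si_clamped,
    call = classify_si(si),
    stringsAsFactors = FALSE
  )
}

#' Sensitive/resistant call from a sensitivity index
#'
#' SI < 250 is sensitive; SI >= 250 is resistant. The published rule leaves
#' SI exactly 250 unassigned; this implementation calls it resistant, the
#' conservative direction for treatment selection.
#'
#' @param si Numeric vector of sensitivity indices.
#' @return Character vector, `"sensitive"` or `"resistant"`.
#' @export
#' @examples
#' classify_si(c(0, 249.9, 250, 600))
classify_si <- function(si) {
  if (any(!is.finite(si)))
    stop("invalid-score: SI must be finite", call. = FALSE)
  ifelse(si < SI_THRESHOLD, "sensitive", "resistant")
}

#' Read long-form plate CSV
#'
#' Expected columns: `specimen_id`, `drug`, `well_role` in
#' \{treated, vehicle, blank\}, `tdc_fraction` (empty for vehicle/blank
#' wells), `replicate`, `signal`. One row per well.
#'
#' @param path CSV file path.
#' @return A data.frame of wells.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "drug", "well_role", "tdc_fraction",
           "replicate", "signal")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("format error: plate CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$well_role), c("treated", "vehicle", "blank"))
  if (length(bad))
    stop("format error: unknown well_role: ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$signal <- as.numeric(df$signal)
  df$tdc_fraction <- suppressWarnings(as.numeric(df$tdc_fraction))
  df
}

# Assemble dose_plate objects from a long-form well table.
plates_from_wells <- function(wells) {
  keys <- unique(wells[wells$well_role == "treated",
                       c("specimen_id", "drug")])
  lapply(seq_len(nrow(keys)), function(i) {
    sid <- keys$specimen_id[i]; drg <- keys$drug[i]
    sub <- wells[wells$specimen_id == sid & wells$drug == drg, ]
    tr <- sub[sub$well_role == "treated", ]
    treated <- split(tr$signal, tr$tdc_fraction)
    dose_plate(sid, drg, treated,
               vehicle = sub$signal[sub$well_role == "vehicle"],
               blank = sub$signal[sub$well_role == "blank"])
  })
}

#' Score plates into an SI table
#'
#' Runs [compute_inhibition()] and [compute_si()] on every specimen x drug
#' plate in a long-form well table (or CSV path) and returns one row per
#' plate with the six inhibition values, both SI variants and the call.
#'
#' @param wells A well table as returned by [read_plate_csv()], a CSV path,
#'   or a list of [dose_plate()] objects.
#' @param use_clamped Sum clamped inhibitions for the reported `si`
#'   (default TRUE); pass FALSE for the unclamped sum.
#' @return A data.frame: `specimen_id`, `drug`, `inhibition_6.25` ...
#'   `inhibition_200`, `si_raw`, `si_clamped`, `si`, `call`.
#' @export
score_plates <- function(wells, use_clamped = TRUE) {
  plates <- if (is.character(wells)) {
    plates_from_wells(read_plate_csv(wells))
  } else if (is.data.frame(wells)) {
    plates_from_wells(wells)
  } else {
    wells
  }
  rows <- lapply(plates, function(p) {
    prof <- compute_inhibition(p)
    res <- compute_si(prof, use_clamped = use_clamped)
    inh <- as.data.frame(as.list(stats::setNames(
      prof$inhibition, paste0("inhibition_", prof$fractions))),
      check.names = FALSE)
    cbind(res[, c("specimen_id", "drug")], inh,
          res[, c("si_raw", "si_clamped", "si", "call")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an SI table as TSV
#'
#' @param si_table Output of [score_plates()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_si_tsv <- function(si_table, path) {
  utils::write.table(si_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Positive-control QC check
#'
#' Positive-control cultures (highly sensitive reference specimens run on
#' every assay batch) must be called sensitive for the drugs they control.
#' This check is configurable, not hard-coded to particular specimen IDs.
#'
#' @param si_table Output of [score_plates()].
#' @param controls data.frame with columns `specimen_id`, `drug` listing the
#'   expected-sensitive control pairs.
#' @return data.frame of failing control pairs (zero rows when QC passes).
#' @export
qc_positive_controls <- function(si_table, controls) {
  m <- merge(controls, si_table, by = c("specimen_id", "drug"))
  m[m$call != "sensitive", c("specimen_id", "drug", "si", "call")]
}
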