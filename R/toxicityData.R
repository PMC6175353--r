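#' Construct a toxicity dataset
#'
#' @param dose doses administered (mg/m2).
#' @param subgroup 0/1 biomarker indicator per record.
#' @param dltWeight (fractional) DLT count per record.
#' @param noDltWeight (fractional) no-DLT count per record.
#' @param isPseudo logical, prior pseudo-data flag (recycled).
#' @return a [ToxicityData-class].
#' @export
ToxicityData <- function(dose, subgroup, dltWeight, noDltWeight,
                         isPseudo = FALSE) {
  n <- length(dose)
  new("ToxicityData", dose = as.numeric(dose),
      subgroup = as.integer(subgroup),
      dltWeight = as.numeric(dltWeight),
      noDltWeight = as.numeric(noDltWeight),
      isPseudo = rep_len(as.logical(isPseudo), n))
}

#' Number of records
#' @param x a [ToxicityData-class].
#' @export
setMethod("length", "ToxicityData", function(x) length(x@dose))

#' Combine toxicity datasets
#' @param x,... [ToxicityData-class] objects.
#' @export
setMethod("c", "ToxicityData", function(x, ...) {
  parts <- c(list(x), list(...))
  new("ToxicityData",
      dose = unlist(lapply(parts, slot, "dose")),
      subgroup = unlist(lapply(parts, slot, "subgroup")),
      dltWeight = unlist(lapply(parts, slot, "dltWeight")),
      noDltWeight = unlist(lapply(parts, slot, "noDltWeight")),
      isPseudo = unlist(lapply(parts, slot, "isPseudo")))
})

#' Trial-data-only view
#'
#' Drops pseudo-data records; this is the view used for the frequentist final
#' dose recommendation.
#'
#' @param data a [ToxicityData-class].
#' @return a [ToxicityData-class] without pseudo records.
#' @export
trialData <- function(data) {
  keep <- !data@isPseudo
  ToxicityData(data@dose[keep], data@subgroup[keep], data@dltWeight[keep],
               data@noDltWeight[keep], data@isPseudo[keep])
}

#' @rdname trialData
#' @export
pseudoData <- function(data) {
  keep <- data@isPseudo
  ToxicityData(data@dose[keep], data@subgroup[keep], data@dltWeight[keep],
               data@noDltWeight[keep], data@isPseudo[keep])
}

#' Subset by subgroup
#' @param data a [ToxicityData-class].
#' @param subgroup 0 or 1.
#' @export
subgroupData <- function(data, subgroup) {
  keep <- data@subgroup == as.integer(subgroup)
  ToxicityData(data@dose[keep], data@subgroup[keep], data@dltWeight[keep],
               data@noDltWeight[keep], data@isPseudo[keep])
}

#' As data.frame (the CSV dialect column layout)
#' @param x a [ToxicityData-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ToxicityData", function(x, ...) {
  data.frame(dose = x@dose, subgroup = x@subgroup, dlt_weight = x@dltWeight,
             no_dlt_weight = x@noDltWeight, is_pseudo = x@isPseudo)
})

setMethod("show", "ToxicityData", function(object) {
  cat(sprintf(
    "ToxicityData: %d records (%.3g DLT / %.3g no-DLT weight; %d pseudo)\n",
    length(object@dose), sum(object@dltWeight), sum(object@noDltWeight),
    sum(object@isPseudo)))
  if (length(object@dose)) print(utils::head(as.data.frame(object), 10L))
  invisible(object)
})

#' Read / write the toxicity-data CSV dialect
#'
#' Headered CSV with columns \code{dose, subgroup, dlt_weight, no_dlt_weight,
#' is_pseudo}. The packaged trial and prior fixtures ship in this format.
#'
#' @param file path to a CSV file.
#' @return [readToxicityData()] returns a [ToxicityData-class].
#' @export
readToxicityData <- function(file) {
  df <- utils::read.csv(file)
  need <- c("dose", "subgroup", "dlt_weight", "no_dlt_weight", "is_pseudo")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed toxicity CSV, missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty toxicity CSV: ", file)
  bad <- which(!is.finite(df$dose) | !is.finite(df$dlt_weight) |
               !is.finite(df$no_dlt_weight))
  if (length(bad))
    stop("malformed toxicity CSV at data line(s) ",
         paste(bad + 1L, collapse = ", "))
  ToxicityData(df$dose, df$subgroup, df$dlt_weight, df$no_dlt_weight,
               as.logical(df$is_pseudo))
}

#' @rdname readToxicityData
#' @param data a [ToxicityData-class] to write.
#' @export
writeToxicityData <- function(data, file) {
  utils::write.csv(as.data.frame(data), file, row.names = FALSE)
  invisible(file)
}

#' The Nicholson et al. paediatric trial toxicity counts
#'
#' DLT counts by dose and biomarker subgroup from the stratified paediatric
#' dose-escalation trial that anchors the worked examples and the simulation
#' scenarios, as a packaged fixture.
#'
#' @return a [ToxicityData-class] with 10 records (no pseudo-data).
#' @examples
#' d <- nicholsonData()
#' sum(d@dltWeight)  # 6 DLTs among 49 patients
#' @export
nicholsonData <- function() {
  readToxicityData(system.file("extdata", "nicholson_trial.csv",
                               package = "doseslab", mustWork = TRUE))
}
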