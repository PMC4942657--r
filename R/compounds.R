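#' Compound registry
#'
#' A compound registry lists the analytes of an assay. Exactly one compound is
#' flagged as the internal reference substance: the single compound for which
#' a calibration standard is prepared in a single-marker (QAMS) assay, and the
#' denominator of every relative correction factor and relative retention
#' time.
#'
#' @param id character vector of short stable compound tokens.
#' @param name display names (defaults to `id`).
#' @param internal_reference the `id` of the internal reference compound.
#' @return A data frame of class `compound_registry` with columns `id`,
#'   `name`, and `is_internal_reference`.
#' @examples
#' compound_registry(c("loganin", "morroniside"), internal_reference = "loganin")
#' @export
compound_registry <- function(id, name = id, internal_reference) {
  reg <- data.frame(
    id = as.character(id),
    name = as.character(name),
    is_internal_reference = as.character(id) == internal_reference,
    stringsAsFactors = FALSE
  )
  class(reg) <- c("compound_registry", "data.frame")
  validate_registry(reg)
}

#' Validate a compound registry
#'
#' Checks the registry invariants: non-empty, unique compound ids, and exactly
#' one internal reference flag.
#'
#' @param registry a `compound_registry` or a data frame with columns `id`,
#'   `name`, `is_internal_reference`.
#' @return the validated registry (invisibly classed as `compound_registry`).
#' @export
validate_registry <- function(registry) {
  if (!is.data.frame(registry) || nrow(registry) == 0L) {
    qams_stop("registry must be a non-empty data frame", "qams_config_error")
  }
  needed <- c("id", "name", "is_internal_reference")
  missing <- setdiff(needed, names(registry))
  if (length(missing)) {
    qams_stop(
      paste0("registry lacks column(s): ", paste(missing, collapse = ", ")),
      "qams_config_error"
    )
  }
  if (anyDuplicated(registry$id)) {
    dup <- unique(registry$id[duplicated(registry$id)])
    qams_stop(
      paste0("duplicate compound id(s): ", paste(dup, collapse = ", ")),
      "qams_config_error"
    )
  }
  n_ref <- sum(registry$is_internal_reference)
  if (n_ref != 1L) {
    qams_stop(
      sprintf("exactly one internal reference required, found %d", n_ref),
      "qams_config_error"
    )
  }
  if (!inherits(registry, "compound_registry")) {
    class(registry) <- c("compound_registry", class(registry))
  }
  invisible(registry)
}

#' Internal reference id of a registry
#' @param registry a `compound_registry`.
#' @return the compound id flagged as internal reference.
#' @export
internal_reference <- function(registry) {
  registry$id[registry$is_internal_reference][1L]
}

#' The eleven polar components of Fructus Corni
#'
#' Default registry for the Fructus Corni (Cornus officinalis) assay: gallic
#' acid, 5-hydroxymethyl-2-furfural, morroniside, cornin, sweroside, loganin,
#' the 7-O-methyl- and 7-O-ethylmorroniside epimer pairs, and cornuside, in
#' elution order, with loganin as the internal reference substance.
#'
#' @return a `compound_registry` of 11 compounds.
#' @export
fructus_corni_registry <- function() {
  compound_registry(
    id = c(
      "gallic_acid", "hmf", "morroniside", "cornin", "sweroside", "loganin",
      "methylmorroniside_7a", "methylmorroniside_7b",
      "ethylmorroniside_7a", "ethylmorroniside_7b", "cornuside"
    ),
    name = c(
      "Gallic acid", "5-Hydroxymethyl-2-furfural", "Morroniside", "Cornin",
      "Sweroside", "Loganin", "7a-O-Methylmorroniside",
      "7b-O-Methylmorroniside", "7a-O-Ethylmorroniside",
      "7b-O-Ethylmorroniside", "Cornuside"
    ),
    internal_reference = "loganin"
  )
}

#' @export
print.compound_registry <- function(x, ...) {
  cat(sprintf(
    "<compound_registry> %d compounds, internal reference: %s\n",
    nrow(x), internal_reference(x)
  ))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
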