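#' Fatty-acid registry
#'
#' The registry is the currency of all panel arithmetic: one row per fatty
#' acid, with a stable `code`, the carbons:double-bonds `shorthand`, and the
#' `family` the acid belongs to. Family membership is a property of the
#' registry, never of an individual sample. The default registry covers the 37
#' fatty acids routinely quantified in bulk-tank milk, with the omega-6 and
#' omega-3 families each defined as exactly seven acids (LA, GLA, 20:2n-6,
#' 20:3n-6, arachidonic, 22:2n-6, 22:4n-6; and ALA, stearidonic, 20:3n-3,
#' EPA, 22:3n-3, DPA, DHA).
#'
#' @param registry A registry tibble, defaulting to [fa_registry()]. Supplying
#'   a custom registry (e.g. read with [read_fa_registry()]) reroutes every
#'   group computation.
#' @return A tibble with columns `code`, `shorthand`, `family`.
#' @examples
#' fa_registry()
#' fa_family_members("omega3")
#' @export
fa_registry <- function() {
  tibble::tribble(
    ~code,      ~shorthand, ~family,
    "4:0",      "4:0",      "saturated",
    "6:0",      "6:0",      "saturated",
    "8:0",      "8:0",      "saturated",
    "10:0",     "10:0",     "saturated",
    "12:0",     "12:0",     "saturated",
    "14:0",     "14:0",     "saturated",
    "15:0",     "15:0",     "saturated",
    "16:0",     "16:0",     "saturated",
    "17:0",     "17:0",     "saturated",
    "18:0",     "18:0",     "saturated",
    "20:0",     "20:0",     "saturated",
    "22:0",     "22:0",     "saturated",
    "24:0",     "24:0",     "saturated",
    "14:1",     "14:1",     "cis-mono",
    "16:1",     "16:1",     "cis-mono",
    "17:1",     "17:1",     "cis-mono",
    "18:1",     "18:1",     "cis-mono",
    "20:1",     "20:1",     "cis-mono",
    "ala",      "18:3n-3",  "omega3",
    "sda",      "18:4n-3",  "omega3",
    "etr_n3",   "20:3n-3",  "omega3",
    "epa",      "20:5n-3",  "omega3",
    "dtr_n3",   "22:3n-3",  "omega3",
    "dpa",      "22:5n-3",  "omega3",
    "dha",      "22:6n-3",  "omega3",
    "la",       "18:2n-6",  "omega6",
    "gla",      "18:3n-6",  "omega6",
    "eda_n6",   "20:2n-6",  "omega6",
    "etr_n6",   "20:3n-6",  "omega6",
    "aa",       "20:4n-6",  "omega6",
    "dda_n6",   "22:2n-6",  "omega6",
    "dte_n6",   "22:4n-6",  "omega6",
    "t14:1",    "t14:1",    "trans",
    "t16:1",    "t16:1",    "trans",
    "t18:1",    "t18:1",    "trans",
    "t18:2",    "t18:2",    "trans",
    "cla",      "c18:2",    "CLA"
  )
}

#' @rdname fa_registry
#' @param family One of `"saturated"`, `"cis-mono"`, `"omega3"`, `"omega6"`,
#'   `"trans"`, `"CLA"`, `"other"`.
#' @export
fa_family_members <- function(family, registry = fa_registry()) {
  validate_fa_registry(registry)
  fam <- match.arg(family,
                   c("saturated", "cis-mono", "omega3", "omega6", "trans",
                     "CLA", "other"))
  registry$code[registry$family == fam]
}

#' @rdname fa_registry
#' @export
validate_fa_registry <- function(registry) {
  required <- c("code", "shorthand", "family")
  missing <- setdiff(required, names(registry))
  if (length(missing) > 0) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lactofat_schema_error")
  }
  if (anyDuplicated(registry$code)) {
    dup <- unique(registry$code[duplicated(registry$code)])
    abort(paste0("duplicate fatty-acid code(s) in registry: ",
                 paste(dup, collapse = ", ")),
          class = "lactofat_schema_error")
  }
  w3 <- registry$code[registry$family == "omega3"]
  w6 <- registry$code[registry$family == "omega6"]
  if (length(intersect(w3, w6)) > 0) {
    abort("omega3 and omega6 families must be disjoint",
          class = "lactofat_schema_error")
  }
  invisible(registry)
}

# Resolve fatty-acid codes against a registry, failing loudly on unknowns.
check_fa_codes <- function(codes, registry = fa_registry()) {
  unknown <- setdiff(codes, registry$code)
  if (length(unknown) > 0) {
    abort(paste0("unknown fatty-acid code(s): ",
                 paste(unknown, collapse = ", ")),
          class = "lactofat_key_error")
  }
  invisible(codes)
}
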