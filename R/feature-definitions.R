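#' Load the pharmacophore feature definition table
#'
#' The perception rules are shipped as a versioned YAML file so they can be
#' audited and substituted. The table defines, per feature type
#' (A/D/H/N/P/R), which substructure rules fire and with which parameters,
#' all interpreted in the pH-7.4 protonation convention (acids ionized,
#' aliphatic amines protonated).
#'
#' @param path Path to a YAML rule table. Default: the table shipped with
#'   the package (`inst/extdata/feature_definitions.yaml`).
#' @return A named list with elements `version`, `ph` and `features`.
#' @examples
#' defs <- feature_definitions()
#' defs$version
#' @export
feature_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_definitions.yaml",
                        package = "combipharm", mustWork = TRUE)
  }
  defs <- yaml::read_yaml(path)
  if (is.null(defs$features) || is.null(defs$version)) {
    abort("feature definition file must contain 'version' and 'features'")
  }
  bad <- setdiff(names(defs$features), c("A", "D", "H", "N", "P", "R"))
  if (length(bad) > 0) {
    abort(paste0("unknown feature type(s) in definitions: ",
                 paste(bad, collapse = ", ")))
  }
  defs
}

# The six-letter feature vocabulary, in canonical order.
ftype_vocab <- function() c("A", "D", "H", "N", "P", "R")
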