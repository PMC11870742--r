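# Residue-level property tables are shipped as plain-text files under
# inst/extdata and cached on first use.

.scale_cache <- new.env(parent = emptyenv())

scale_table <- function() {
  if (is.null(.scale_cache$tab)) {
    path <- system.file("extdata", "aa_scales.tsv", package = "antigenome")
    tab <- read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$residue
    .scale_cache$tab <- tab
  }
  .scale_cache$tab
}

#' Amino-acid property scales
#'
#' Returns a named numeric vector (one value per standard residue) for a
#' published residue-level scale.  Available scales:
#' \describe{
#'   \item{kyte_doolittle}{Kyte-Doolittle hydropathy (GRAVY components).}
#'   \item{parker}{Parker-Guo-Hodges HPLC hydrophilicity.}
#'   \item{emini_surface}{fractional surface probabilities used by the
#'     Emini accessibility product.}
#'   \item{cf_helix, cf_sheet, cf_turn}{Chou-Fasman conformational
#'     propensities P\eqn{\alpha}, P\eqn{\beta}, P\eqn{turn}.}
#'   \item{cf_turn_f1 .. cf_turn_f4}{Chou-Fasman positional bend
#'     frequencies f(i) .. f(i+3).}
#' }
#'
#' @param name scale name (see above).
#' @return named numeric vector over the 20 standard residues.
#' @export
#' @examples
#' aa_scale("kyte_doolittle")[["I"]]  # 4.5
aa_scale <- function(name) {
  tab <- scale_table()
  if (!name %in% colnames(tab)[-1]) {
    stop("unknown scale '", name, "'; available: ",
         paste(colnames(tab)[-1], collapse = ", "))
  }
  setNames(tab[[name]], tab$residue)
}

#' Ionisable-group pKa set
#'
#' The EMBOSS pKa values used by [isoelectric_point()], read from the
#' package data file `pka_emboss.tsv`.
#'
#' @return data frame with columns `group`, `pka`, `charge`.
#' @export
pka_set <- function() {
  if (is.null(.scale_cache$pka)) {
    path <- system.file("extdata", "pka_emboss.tsv", package = "antigenome")
    .scale_cache$pka <- read.delim(path, stringsAsFactors = FALSE)
  }
  .scale_cache$pka
}
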