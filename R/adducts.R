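# Adduct specifications.  An adduct table is a plain data.frame with
# columns name, polarity, multimer, delta_mass, charge; delta_mass is the
# signed Da added to multimer x M and is already electron-corrected, so
# adduct m/z = (multimer * M + delta_mass) / charge needs no further
# correction.

.adductRow <- function(name, polarity, multimer, delta_mass, charge = 1L) {
  data.frame(name = name, polarity = polarity, multimer = as.integer(multimer),
             delta_mass = delta_mass, charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

# ionizing-species masses assembled from the element table + electron
.H2O   <- function() monoisotopicMass(c(H = 2L, O = 1L))
.NH4p  <- function() monoisotopicMass(c(N = 1L, H = 4L)) - ELECTRON_MASS
.Nap   <- function() MONOISOTOPIC_MASS[["Na"]] - ELECTRON_MASS
.Kp    <- function() MONOISOTOPIC_MASS[["K"]] - ELECTRON_MASS
.Clm   <- function() MONOISOTOPIC_MASS[["Cl"]] + ELECTRON_MASS
.HCOOm <- function() monoisotopicMass(c(C = 1L, H = 1L, O = 2L)) + ELECTRON_MASS
.OAcm  <- function() monoisotopicMass(c(C = 2L, H = 3L, O = 2L)) + ELECTRON_MASS

#' Built-in adduct table for one ionization polarity
#'
#' The preset ionization rules searched within a peak group: protonated /
#' deprotonated species, alkali and ammonium adducts, water neutral
#' losses, formate and acetate adducts in negative mode, and dimers.
#' All species are singly charged by default; the table format supports
#' higher charges.  Users can extend or replace the table (see
#' [readAdductTable()]).
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame with columns `name`, `polarity`, `multimer`,
#'   `delta_mass` (signed Da, electron-corrected), `charge`.
#' @examples
#' defaultAdducts("positive")
#' @export
defaultAdducts <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  p <- PROTON_MASS
  tab <- if (polarity == "positive") rbind(
    .adductRow("[M+H]+",      "positive", 1L,  p),
    .adductRow("[M+Na]+",     "positive", 1L,  .Nap()),
    .adductRow("[M+K]+",      "positive", 1L,  .Kp()),
    .adductRow("[M+NH4]+",    "positive", 1L,  .NH4p()),
    .adductRow("[M-H2O+H]+",  "positive", 1L,  p - .H2O()),
    .adductRow("[2M+H]+",     "positive", 2L,  p),
    .adductRow("[2M+Na]+",    "positive", 2L,  .Nap())
  ) else rbind(
    .adductRow("[M-H]-",      "negative", 1L, -p),
    .adductRow("[M+Cl]-",     "negative", 1L,  .Clm()),
    .adductRow("[M-H2O-H]-",  "negative", 1L, -p - .H2O()),
    .adductRow("[M+HCOO]-",   "negative", 1L,  .HCOOm()),
    .adductRow("[M+CH3COO]-", "negative", 1L,  .OAcm()),
    .adductRow("[2M-H]-",     "negative", 2L, -p)
  )
  validateAdducts(tab)
}

validateAdducts <- function(adducts) {
  req <- c("name", "polarity", "multimer", "delta_mass", "charge")
  miss <- setdiff(req, names(adducts))
  if (length(miss))
    stop("adduct table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(adducts) == 0L) stop("adduct table is empty")
  if (anyDuplicated(adducts$name)) stop("adduct names must be unique")
  stopifnot(all(adducts$multimer >= 1L), all(adducts$charge >= 1L),
            all(is.finite(adducts$delta_mass)),
            all(adducts$polarity %in% c("positive", "negative")))
  adducts
}

#' Read a user-supplied adduct table
#'
#' CSV/TSV with columns `name, polarity, multimer, delta_mass, charge`;
#' `delta_mass` must already be electron-corrected (the mass of the
#' ionizing species as it changes the ion, e.g. +1.007276 for `[M+H]+`).
#'
#' @param path File path; delimiter sniffed from the header line.
#' @return Validated adduct data.frame.
#' @export
readAdductTable <- function(path) {
  sep <- sniffSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  if (all(c("multimer", "charge") %in% names(tab))) {
    tab$multimer <- as.integer(tab$multimer)
    tab$charge <- as.integer(tab$charge)
  }
  validateAdducts(tab)
}

#' Theoretical m/z of an adduct of a molecule
#'
#' `(multimer * M + delta_mass) / charge` where M is the neutral
#' monoisotopic mass.  Vectorized over adduct rows.
#'
#' @param f Formula string, named count vector, or a neutral
#'   monoisotopic mass in Da.
#' @param adducts One or more rows of an adduct table.
#' @return Numeric vector of m/z values, named by adduct.
#' @examples
#' adductMz("C5H9NO4", defaultAdducts("positive"))
#' @export
adductMz <- function(f, adducts) {
  mass <- if (is.numeric(f) && is.null(names(f))) f else monoisotopicMass(f)
  stopifnot(length(mass) == 1L, mass > 0)
  mz <- (adducts$multimer * mass + adducts$delta_mass) / adducts$charge
  if (any(mz <= 0))
    stop("invalid adduct: resulting m/z <= 0 for ",
         paste(adducts$name[mz <= 0], collapse = ", "))
  stats::setNames(mz, adducts$name)
}
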