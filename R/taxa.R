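#' Canonical taxon vocabulary for the knotweed complex
#'
#' The sixteen plant types of the herbarium study: five interbreeding
#' species (including three varieties of Japanese Knotweed), six hybrids,
#' and five more distantly related Polygonaceae "out species". Published
#' sources mix *Reynoutria* and *Fallopia* genus names for the same plants;
#' [normalize_taxon()] maps the printed variants onto this single
#' vocabulary so class labels are consistent for classification.
#'
#' @return character vector of the 16 canonical labels.
#' @seealso [normalize_taxon()]
#' @export
knotweed_taxa <- function() {
  c("Reynoutria japonica var. japonica",
    "Reynoutria japonica var. compacta",
    "Reynoutria japonica var. uzenensis",
    "Fallopia baldschuanica",
    "Reynoutria sachalinensis",
    "Reynoutria japonica x baldschuanica",
    "Reynoutria x bohemica",
    "Reynoutria sachalinensis x Fallopia baldschuanica",
    "Reynoutria japonica var. compacta x baldschuanica",
    "Reynoutria japonica var. compacta x sachalinensis",
    "Reynoutria japonica var. japonica x compacta",
    "Fallopia cilinodis",
    "Fallopia convolvulus",
    "Fallopia multiflora",
    "Fagopyrum esculentum",
    "Rumex acetosella")
}

# printed variants -> canonical label, keyed on a squashed form
# (lowercase, genus synonyms collapsed, punctuation/whitespace removed)
taxon_synonyms <- function() {
  canon <- knotweed_taxa()
  syn <- c(
    "Fallopia japonica"                                        = canon[1],
    "Fallopia japonica var. japonica"                          = canon[1],
    "Polygonum cuspidatum"                                     = canon[1],
    "Japanese Knotweed"                                        = canon[1],
    "Fallopia japonica var. compacta"                          = canon[2],
    "Fallopia japonica var. uzenensis"                         = canon[3],
    "Polygonum baldschuanicum"                                 = canon[4],
    "Russian vine"                                             = canon[4],
    "Fallopia sachalinensis"                                   = canon[5],
    "Giant Knotweed"                                           = canon[5],
    "Fallopia japonica x baldschuanica"                        = canon[6],
    "Reynoutria japonica var. japonica x Fallopia baldschuanica" = canon[6],
    "Fallopia x bohemica"                                      = canon[7],
    "Reynoutria japonica x sachalinensis"                      = canon[7],
    "Reynoutria japonica x sachalinensis (Reynoutria x bohemica)" = canon[7],
    "Reynoutria japonica var. japonica x sachalinensis"        = canon[7],
    "Bohemian Knotweed"                                        = canon[7],
    "Fallopia sachalinensis x Fallopia baldschuanica"          = canon[8],
    "Reynoutria sachalinensis x baldschuanica"                 = canon[8],
    "Fallopia japonica var. compacta x baldschuanica"          = canon[9],
    "Reynoutria japonica var. compacta x Fallopia baldschuanica" = canon[9],
    "Reynoutria japonica var. compacta x Reynoutria sachalinensis" = canon[10],
    "Fallopia japonica var. compacta x sachalinensis"          = canon[10],
    "Reynoutria japonica var. japonica x Reynoutria japonica var. compacta" = canon[11],
    "Fallopia japonica var. japonica x compacta"               = canon[11],
    "Buckwheat"                                                = canon[15],
    "Sheep's Sorrel"                                           = canon[16]
  )
  keys <- c(vapply(canon, squash_taxon, ""), vapply(names(syn), squash_taxon, ""))
  vals <- c(canon, unname(syn))
  keep <- !duplicated(keys)
  stats::setNames(vals[keep], keys[keep])
}

squash_taxon <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[*'‘’.]", "", x)
  x <- gsub("×", "x", x)       # multiplication sign -> x
  x <- gsub("\\bvar\\b", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Normalise taxon labels to the canonical vocabulary
#'
#' Maps the genus-synonym spellings found in the literature (e.g.
#' "Fallopia japonica var. compacta x baldschuanica",
#' "Reynoutria japonica x sachalinensis (Reynoutria x bohemica)") onto the
#' 16 canonical labels of [knotweed_taxa()]. Matching is insensitive to
#' case, punctuation and the "var." marker. Labels with no known synonym
#' (e.g. synthetic class names) are returned unchanged.
#'
#' @param x character vector of taxon labels.
#' @return character vector of the same length, canonical where known.
#' @examples
#' normalize_taxon("Fallopia japonica var. compacta")
#' normalize_taxon("class01")  # passes through
#' @export
normalize_taxon <- function(x) {
  map <- taxon_synonyms()
  key <- vapply(as.character(x), squash_taxon, "")
  hit <- map[key]
  out <- ifelse(is.na(hit), as.character(x), hit)
  unname(out)
}
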