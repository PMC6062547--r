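# AAindex accession choices for the 14 named physicochemical properties.
# The property names fix the concept, not a unique AAindex entry; the
# accessions below are the classical scales for each name (Fasman 1976
# handbook values for the thermodynamic/chemical constants, Hutchens 1970
# for the entropic ones). Values are pulled from the AAindex copy bundled
# with seqinr at load time, not re-typed here.
AAINDEX14_ACCESSIONS <- c(
  hydrophobicity        = "ARGP820101", # Hydrophobicity index (Argos 1982)
  solvent_accessibility = "JANJ780101", # Average accessible surface area (Janin 1978)
  polarity              = "GRAR740102", # Polarity (Grantham 1974)
  polarizability        = "CHAM820101", # Polarizability parameter (Charton 1982)
  accessibility         = "CHOC760102", # Accessible surface area, folded protein (Chothia 1976)
  pk_n                  = "FASG760104", # pK-N (Fasman 1976)
  pk_c                  = "FASG760105", # pK-C (Fasman 1976)
  melting_point         = "FASG760102", # Melting point (Fasman 1976)
  molecular_weight      = "FASG760101", # Molecular weight (Fasman 1976)
  optical_rotation      = "FASG760103", # Optical rotation (Fasman 1976)
  net_charge            = "KLEP840101", # Net charge (Klein 1984)
  entropy_of_formation  = "HUTJ700103", # Entropy of formation (Hutchens 1970)
  heat_capacity         = "HUTJ700101", # Heat capacity (Hutchens 1970)
  absolute_entropy      = "HUTJ700102"  # Absolute entropy (Hutchens 1970)
)

# The 8 high-quality indices: representatives of the 8 groups obtained by
# fuzzy clustering of 544 AAindex properties.
HQI8_ACCESSIONS <- c(
  BLAM930101 = "BLAM930101",
  BIOV880101 = "BIOV880101",
  MAXF760101 = "MAXF760101",
  TSAJ990101 = "TSAJ990101",
  NAKH920108 = "NAKH920108",
  CEDJ970104 = "CEDJ970104",
  LIFS790101 = "LIFS790101",
  MIYS990104 = "MIYS990104"
)

# Cache: the AAindex lookup is pure, so build the default table once per
# session.
.property_cache <- new.env(parent = emptyenv())

#' Amino-acid property table for the AAindex and HQI feature blocks
#'
#' Builds the per-residue value table used by [encode_aaindex()] and
#' [encode_hqi()]: 14 physicochemical properties (hydrophobicity, solvent
#' accessibility, polarity, polarizability, accessibility, pK-N, pK-C,
#' melting point, molecular weight, optical rotation, net charge of side
#' chains, entropy of formation, heat capacity, absolute entropy) and the 8
#' high-quality indices BLAM930101, BIOV880101, MAXF760101, TSAJ990101,
#' NAKH920108, CEDJ970104, LIFS790101, MIYS990104. Values come from the
#' AAindex database (the copy distributed with \pkg{seqinr}).
#'
#' Because the raw scales have heterogeneous units (molecular weight vs pK),
#' each property is min-max scaled to \[0, 1\] across the 20 canonical
#' residues by default; the padding pseudo-residue X always maps to an
#' all-zero row.
#'
#' @param scale If `TRUE` (default), min-max scale every property to
#'   \[0, 1\] over the 20 canonical residues.
#' @return An object of class `aa_property_table`: a list with matrices
#'   `aaindex14` (21 x 14) and `hqi8` (21 x 8), rows named by the 21-letter
#'   alphabet (X row all zero), columns named by property.
#' @examples
#' tab <- aa_property_table()
#' tab$aaindex14["C", "molecular_weight"]
#' all(tab$hqi8["X", ] == 0)
#' @export
aa_property_table <- function(scale = TRUE) {
  key <- if (scale) "scaled" else "raw"
  if (!is.null(.property_cache[[key]])) {
    return(.property_cache[[key]])
  }
  aaidx <- get_aaindex_db()
  tab <- list(
    aaindex14 = build_property_matrix(aaidx, AAINDEX14_ACCESSIONS, scale),
    hqi8      = build_property_matrix(aaidx, HQI8_ACCESSIONS, scale)
  )
  class(tab) <- "aa_property_table"
  .property_cache[[key]] <- tab
  tab
}

#' @noRd
get_aaindex_db <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  env$aaindex
}

#' @noRd
build_property_matrix <- function(aaidx, accessions, scale) {
  headers <- vapply(aaidx, function(e) e$H, character(1))
  m <- matrix(0, nrow = 21L, ncol = length(accessions),
              dimnames = list(AA21, names(accessions)))
  for (j in seq_along(accessions)) {
    hit <- which(headers == accessions[[j]])
    if (length(hit) != 1L) {
      stop("AAindex accession not found: ", accessions[[j]])
    }
    vals <- aaidx[[hit]]$I
    # seqinr names residues by three-letter code; convert to one-letter
    one <- toupper(vapply(names(vals), function(a) seqinr::a(a), character(1)))
    if (!setequal(one, AA20) || anyNA(vals)) {
      stop("AAindex entry ", accessions[[j]],
           " does not cover the 20 canonical residues with finite values")
    }
    v <- as.numeric(vals)[match(AA20, one)]
    if (scale) {
      rng <- range(v)
      v <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else rep(0, 20L)
    }
    m[AA20, j] <- v
  }
  m["X", ] <- 0
  m
}

#' @export
print.aa_property_table <- function(x, ...) {
  cat("Amino-acid property table\n")
  cat("  aaindex14:", ncol(x$aaindex14), "properties x",
      nrow(x$aaindex14), "residues\n")
  cat("  hqi8:     ", ncol(x$hqi8), "indices x", nrow(x$hqi8), "residues\n")
  cat("  X maps to all-zero rows\n")
  invisible(x)
}
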