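#' @keywords internal
aa3 <- c(
  Ser = "S", Arg = "R", Leu = "L", Pro = "P", Thr = "T", Ala = "A", Val = "V",
  Gly = "G", Ile = "I", Phe = "F", Tyr = "Y", Cys = "C", His = "H", Gln = "Q",
  Asn = "N", Lys = "K", Asp = "D", Glu = "E", Met = "M", Trp = "W"
)

.grantham_build <- function() {
  aas <- names(aa3)
  # upper triangle of Grantham's (1974) physicochemical distance table, in the
  # original row order Ser..Trp
  upper <- list(
    Ser = c(Arg = 110, Leu = 145, Pro = 74, Thr = 58, Ala = 99, Val = 124,
            Gly = 56, Ile = 142, Phe = 155, Tyr = 144, Cys = 112, His = 89,
            Gln = 68, Asn = 46, Lys = 121, Asp = 65, Glu = 80, Met = 135,
            Trp = 177),
    Arg = c(Leu = 102, Pro = 103, Thr = 71, Ala = 112, Val = 96, Gly = 125,
            Ile = 97, Phe = 97, Tyr = 77, Cys = 180, His = 29, Gln = 43,
            Asn = 86, Lys = 26, Asp = 96, Glu = 54, Met = 91, Trp = 101),
    Leu = c(Pro = 98, Thr = 92, Ala = 96, Val = 32, Gly = 138, Ile = 5,
            Phe = 22, Tyr = 36, Cys = 198, His = 99, Gln = 113, Asn = 153,
            Lys = 107, Asp = 172, Glu = 138, Met = 15, Trp = 61),
    Pro = c(Thr = 38, Ala = 27, Val = 68, Gly = 42, Ile = 95, Phe = 114,
            Tyr = 110, Cys = 169, His = 77, Gln = 76, Asn = 91, Lys = 103,
            Asp = 108, Glu = 93, Met = 87, Trp = 147),
    Thr = c(Ala = 58, Val = 69, Gly = 59, Ile = 89, Phe = 103, Tyr = 92,
            Cys = 149, His = 47, Gln = 42, Asn = 65, Lys = 78, Asp = 85,
            Glu = 65, Met = 81, Trp = 128),
    Ala = c(Val = 64, Gly = 60, Ile = 94, Phe = 113, Tyr = 112, Cys = 195,
            His = 86, Gln = 91, Asn = 111, Lys = 106, Asp = 126, Glu = 107,
            Met = 84, Trp = 148),
    Val = c(Gly = 109, Ile = 29, Phe = 50, Tyr = 55, Cys = 192, His = 84,
            Gln = 96, Asn = 133, Lys = 97, Asp = 152, Glu = 121, Met = 21,
            Trp = 88),
    Gly = c(Ile = 135, Phe = 153, Tyr = 147, Cys = 159, His = 98, Gln = 87,
            Asn = 80, Lys = 127, Asp = 94, Glu = 98, Met = 127, Trp = 184),
    Ile = c(Phe = 21, Tyr = 33, Cys = 198, His = 94, Gln = 109, Asn = 149,
            Lys = 102, Asp = 168, Glu = 134, Met = 10, Trp = 61),
    Phe = c(Tyr = 22, Cys = 205, His = 100, Gln = 116, Asn = 158, Lys = 102,
            Asp = 177, Glu = 140, Met = 28, Trp = 40),
    Tyr = c(Cys = 194, His = 83, Gln = 99, Asn = 143, Lys = 85, Asp = 160,
            Glu = 122, Met = 36, Trp = 37),
    Cys = c(His = 174, Gln = 154, Asn = 139, Lys = 202, Asp = 154, Glu = 170,
            Met = 196, Trp = 215),
    His = c(Gln = 24, Asn = 68, Lys = 32, Asp = 81, Glu = 40, Met = 87,
            Trp = 115),
    Gln = c(Asn = 46, Lys = 53, Asp = 61, Glu = 29, Met = 101, Trp = 130),
    Asn = c(Lys = 94, Asp = 23, Glu = 42, Met = 142, Trp = 174),
    Lys = c(Asp = 101, Glu = 56, Met = 95, Trp = 110),
    Asp = c(Glu = 45, Met = 160, Trp = 181),
    Glu = c(Met = 126, Trp = 152),
    Met = c(Trp = 67)
  )
  m <- matrix(0L, 20, 20, dimnames = list(aas, aas))
  for (a in names(upper)) {
    for (b in names(upper[[a]])) {
      m[a, b] <- m[b, a] <- as.integer(upper[[a]][[b]])
    }
  }
  m
}

#' Grantham amino-acid distance matrix
#'
#' The 20 x 20 symmetric matrix of physicochemical distances between the
#' standard amino acids from Grantham (1974), indexed by three-letter residue
#' codes (`"Ser"`, `"Arg"`, ...). Distances range from 5 (Leu/Ile) to 215
#' (Cys/Trp); the diagonal is 0. Distances above 80 are treated as
#' potentially deleterious by the prioritization cascade.
#'
#' @format Integer matrix with residue names as dimnames.
#' @export
grantham_matrix <- .grantham_build()

.normalize_aa <- function(x) {
  x <- trimws(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    a <- x[[i]]
    if (nchar(a) == 1L) {
      if (a == "*") {
        out[[i]] <- "Ter"
        next
      }
      hit <- names(aa3)[match(toupper(a), aa3)]
      if (is.na(hit)) stop("unknown amino-acid code: '", a, "'", call. = FALSE)
      out[[i]] <- hit
    } else {
      a <- paste0(toupper(substr(a, 1, 1)), tolower(substr(a, 2, nchar(a))))
      if (a %in% c("Ter", "*")) {
        out[[i]] <- "Ter"
      } else if (a %in% names(aa3)) {
        out[[i]] <- a
      } else {
        stop("unknown amino-acid code: '", x[[i]], "'", call. = FALSE)
      }
    }
  }
  out
}

#' Grantham distance between two residues
#'
#' Looks up the Grantham (1974) physicochemical distance for a residue pair.
#' Accepts one- or three-letter codes. Only the 20 standard amino acids are
#' valid; stop codons are rejected (use [variant_grantham()] for the
#' variant-level convention, which assigns sentinels to stop gain/loss).
#'
#' @param ref_aa,alt_aa Residue codes (vectorized).
#' @return Integer vector of distances; 0 on identity.
#' @examples
#' grantham_score("Leu", "Pro")  # 98
#' grantham_score("Cys", "Phe")  # 205
#' @export
grantham_score <- function(ref_aa, alt_aa) {
  a <- .normalize_aa(ref_aa)
  b <- .normalize_aa(alt_aa)
  if (any(a == "Ter") || any(b == "Ter")) {
    stop("Grantham distance is undefined for stop codons; ",
         "see variant_grantham() for the sentinel convention", call. = FALSE)
  }
  as.integer(grantham_matrix[cbind(a, b)])
}

#' Variant-level Grantham value with stop/frameshift sentinels
#'
#' Applies the tabulation convention used in rare-variant reports: missense
#' changes get the true Grantham distance, stop gains and stop losses get the
#' sentinel 1000, and frameshift / splice / other non-substitution changes get
#' 0. Sentinels never drive deleteriousness on their own because the
#' variant-type rule fires first for those classes.
#'
#' @param variant_type One of the [classify_variant_type()] categories.
#' @param ref_aa,alt_aa Residues, required only for missense.
#' @return Integer scalar.
#' @export
variant_grantham <- function(variant_type, ref_aa = NULL, alt_aa = NULL) {
  switch(variant_type,
    missense = {
      if (is.null(ref_aa) || is.null(alt_aa)) {
        stop("missense variants need ref_aa and alt_aa", call. = FALSE)
      }
      grantham_score(ref_aa, alt_aa)
    },
    nonsense = 1000L,
    stop_loss = 1000L,
    synonymous = 0L,
    0L
  )
}
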