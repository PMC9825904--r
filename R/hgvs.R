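# HGVS parsing: the subset of the protein- and coding-level grammar that
# appears in clinical variant tables (substitution, stop gain, frameshift,
# stop-loss extension, synonymous, simple inframe indels). Inversions and
# delins with sequence payloads are out of scope.

#' Parse a protein-level HGVS string
#'
#' Handles the notation used in clinical rare-variant tables:
#' * substitution `p.Leu16Pro` (including stop gain `p.Lys289*` / `p.Lys289Ter`)
#' * synonymous `p.Leu16=`
#' * frameshift `p.Ala152Glnfs*8` (also bare `p.Ala152fs`)
#' * stop loss with extension `p.*1664Trpext*58` / `p.Ter1664TrpextTer24`
#' * inframe deletion/duplication/insertion `p.Lys35del`, `p.Lys35_Val38dup`
#'
#' @param hgvs_p String beginning `"p."`.
#' @return A list with class `"hgvs_p"`: `kind` (one of `"substitution"`,
#'   `"synonymous"`, `"stop_gain"`, `"frameshift"`, `"stop_loss"`,
#'   `"inframe_indel"`), `position`, `ref_aa`, `alt_aa` (three-letter codes,
#'   `"Ter"` for stop), `fs_term` (frameshift stop offset or `NA`),
#'   `ext` (extension length or `NA`), and `raw`.
#' @examples
#' parse_hgvs_p("p.Leu16Pro")
#' parse_hgvs_p("p.Lys289*")
#' parse_hgvs_p("p.*1664Trpext*58")
#' @export
parse_hgvs_p <- function(hgvs_p) {
  raw <- hgvs_p
  stopifnot(is.character(hgvs_p), length(hgvs_p) == 1L)
  if (!startsWith(hgvs_p, "p.")) {
    stop("not a protein-level HGVS string: '", raw, "'", call. = FALSE)
  }
  body <- sub("^p\\.", "", hgvs_p)
  body <- gsub("[()]", "", body)
  res <- function(kind, position = NA_integer_, ref_aa = NA_character_,
                  alt_aa = NA_character_, fs_term = NA_integer_,
                  ext = NA_integer_) {
    structure(list(kind = kind, position = as.integer(position),
                   ref_aa = ref_aa, alt_aa = alt_aa,
                   fs_term = as.integer(fs_term), ext = as.integer(ext),
                   raw = raw),
              class = "hgvs_p")
  }
  AA <- "([A-Z][a-z]{2})"

  # stop-loss extension: p.*1664Trpext*58 or p.Ter1664TrpextTer24
  m <- regmatches(body, regexec(paste0("^(\\*|Ter)(\\d+)", AA,
                                       "ext(\\*|Ter)(\\d+)$"), body))[[1]]
  if (length(m)) {
    return(res("stop_loss", m[3], "Ter", .normalize_aa(m[4]), ext = m[6]))
  }
  # frameshift: p.Ala152Glnfs*8 / p.Lys35Valfs*20 / p.Ala152fs
  m <- regmatches(body, regexec(paste0("^", AA, "(\\d+)(", AA,
                                       ")?fs((\\*|Ter)(\\d+))?$"), body))[[1]]
  if (length(m)) {
    alt <- if (nzchar(m[4])) .normalize_aa(m[4]) else NA_character_
    fs <- if (nzchar(m[8])) m[8] else NA_integer_
    return(res("frameshift", m[3], .normalize_aa(m[2]), alt, fs_term = fs))
  }
  # synonymous: p.Leu16=
  m <- regmatches(body, regexec(paste0("^", AA, "(\\d+)=$"), body))[[1]]
  if (length(m)) {
    aa <- .normalize_aa(m[2])
    return(res("synonymous", m[3], aa, aa))
  }
  # substitution (incl. stop gain): p.Leu16Pro, p.Lys289*, p.Lys289Ter
  m <- regmatches(body, regexec(paste0("^", AA, "(\\d+)(", AA,
                                       "|\\*|Ter)$"), body))[[1]]
  if (length(m)) {
    alt <- .normalize_aa(m[4])
    kind <- if (alt == "Ter") "stop_gain" else "substitution"
    return(res(kind, m[3], .normalize_aa(m[2]), alt))
  }
  # inframe indel: p.Lys35del, p.Lys35_Val38del, ...dup, ...ins...
  m <- regmatches(body, regexec(paste0("^", AA, "(\\d+)(_", AA,
                                       "(\\d+))?(del|dup|ins[A-Za-z]*)$"),
                                body))[[1]]
  if (length(m)) {
    return(res("inframe_indel", m[3], .normalize_aa(m[2])))
  }
  stop("unparsable protein HGVS: '", raw, "'", call. = FALSE)
}

#' Intronic offset of a coding-level HGVS string
#'
#' Extracts the signed intronic offset from a `c.` description, e.g.
#' `"c.2437-2A>G"` gives `-2` and `"c.350+6T>G"` gives `+6`. Exonic positions
#' give `NA`. For range descriptions (`c.x_ydel`) the first position's offset
#' is used. Unparsable strings give `NA` with a warning rather than an error.
#'
#' @param hgvs_c String beginning `"c."`.
#' @return Integer offset or `NA_integer_`.
#' @export
splice_offset <- function(hgvs_c) {
  stopifnot(is.character(hgvs_c), length(hgvs_c) == 1L)
  if (!startsWith(hgvs_c, "c.")) {
    stop("not a coding-level HGVS string: '", hgvs_c, "'", call. = FALSE)
  }
  body <- sub("^c\\.", "", hgvs_c)
  body <- gsub("\\s", "", body)
  # first position token: optional UTR marker (* or -), digits, optional offset
  m <- regmatches(body, regexec("^(\\*?-?\\d+)([+-]\\d+)?", body))[[1]]
  if (!length(m) || !nzchar(m[2])) {
    warning("could not parse coding HGVS position: '", hgvs_c, "'")
    return(NA_integer_)
  }
  if (nzchar(m[3])) as.integer(m[3]) else NA_integer_
}

#' Variant-type vocabulary
#' @keywords internal
variant_type_levels <- c("missense", "nonsense", "frameshift", "stop_loss",
                         "canonical_splice", "splice_region", "synonymous",
                         "inframe_indel", "other")

.consequence_type_map <- c(
  stop_gained = "nonsense",
  nonsense = "nonsense",
  frameshift_variant = "frameshift",
  frameshift = "frameshift",
  stop_lost = "stop_loss",
  stop_loss = "stop_loss",
  splice_acceptor_variant = "canonical_splice",
  splice_acceptor = "canonical_splice",
  splice_donor_variant = "canonical_splice",
  splice_donor = "canonical_splice",
  splice_region_variant = "splice_region",
  splice_region = "splice_region",
  missense_variant = "missense",
  missense = "missense",
  synonymous_variant = "synonymous",
  synonymous = "synonymous",
  inframe_deletion = "inframe_indel",
  inframe_insertion = "inframe_indel",
  inframe_indel = "inframe_indel"
)

#' Classify a variant into the prioritization type vocabulary
#'
#' Assigns exactly one of: missense, nonsense, frameshift, stop_loss,
#' canonical_splice, splice_region, synonymous, inframe_indel, other.
#' Protein-level notation takes precedence; when no protein change is
#' available the intronic offset of the coding change decides splice class
#' (|offset| 1-2 = canonical splice, 3-8 = splice region, deeper = other);
#' the consequence term is the fallback. Deterministic for identical inputs.
#'
#' @param hgvs_c Coding HGVS string or `NA`.
#' @param hgvs_p Protein HGVS string or `NA`.
#' @param consequence Consequence term (VEP-style or short form) or `NA`.
#' @return Single type string.
#' @examples
#' classify_variant_type("c.865A>T", "p.Lys289*", "stop_gained")   # nonsense
#' classify_variant_type("c.2437-2A>G", NA, "splice_acceptor")     # canonical_splice
#' classify_variant_type("c.350+6T>G", NA, "splice_region")        # splice_region
#' @export
classify_variant_type <- function(hgvs_c = NA, hgvs_p = NA, consequence = NA) {
  has <- function(x) !is.null(x) && length(x) == 1L && !is.na(x) && nzchar(x)
  if (!has(hgvs_c) && !has(hgvs_p) && !has(consequence)) {
    stop("cannot classify a variant with no HGVS strings and no consequence",
         call. = FALSE)
  }
  if (has(hgvs_p)) {
    p <- tryCatch(parse_hgvs_p(hgvs_p), error = function(e) NULL)
    if (!is.null(p)) {
      out <- switch(p$kind,
        substitution = if (identical(p$ref_aa, p$alt_aa)) "synonymous" else "missense",
        stop_gain = "nonsense",
        frameshift = "frameshift",
        stop_loss = "stop_loss",
        synonymous = "synonymous",
        inframe_indel = "inframe_indel"
      )
      if (!is.null(out)) return(out)
    }
  }
  if (has(hgvs_c)) {
    off <- suppressWarnings(splice_offset(hgvs_c))
    if (!is.na(off)) {
      a <- abs(off)
      if (a <= 2L) return("canonical_splice")
      if (a <= 8L) return("splice_region")
      return("other")
    }
  }
  if (has(consequence)) {
    key <- tolower(trimws(consequence))
    hit <- .consequence_type_map[[key]]
    if (!is.null(hit)) return(hit)
  }
  "other"
}
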