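#' Default species-prefix table
#'
#' Three- or four-letter species prefixes recognized (and stripped) in front
#' of a mature miRNA name, e.g. `bta-` (cattle), `ssc-` (pig), `oni-`
#' (Nile tilapia), `spu-` (sea urchin dialects used for sea cucumber reads),
#' `efu-`, `pmi-`. Unknown lowercase 3-4 letter prefixes are still stripped,
#' with a warning, so that one unlisted dialect cannot split an identity.
#'
#' @return Character vector of known prefixes (lowercase, no trailing dash).
#' @export
mirna_prefixes <- function() {
  c("bta", "ssc", "oar", "chi", "ocu", "cap", "oni", "spu", "efu", "pmi",
    "hsa", "mmu", "gga", "bbu", "cja")
}

# Internal single-name parser. Returns list(base, arm) or signals an error.
parse_one_mirna <- function(raw, prefixes, warn_unknown = TRUE) {
  name <- trimws(raw)
  if (!nzchar(name)) {
    stop("empty miRNA name", call. = FALSE)
  }
  # duplicate-read annotations after an underscore ("_1", "_2") are dropped
  name <- sub("_.*$", "", name)

  # strip one species prefix ahead of the miR/let stem
  m <- regmatches(name, regexec("^([A-Za-z]{3,4})-(?=[Mm][Ii][Rr]|[Ll][Ee][Tt])",
                                name, perl = TRUE))[[1]]
  if (length(m) == 2L) {
    pfx <- tolower(m[2])
    if (!(pfx %in% prefixes) && warn_unknown) {
      warning(sprintf("stripping unrecognized species prefix '%s-' from '%s'",
                      pfx, raw), call. = FALSE)
    }
    name <- sub("^[A-Za-z]{3,4}-", "", name)
  }

  stem <- regmatches(name, regexec("^([Mm][Ii][Rr]|[Ll][Ee][Tt])([-0-9].*)$",
                                   name))[[1]]
  if (length(stem) != 3L) {
    stop(sprintf("'%s' does not look like a mature miRNA name (no miR/let stem)",
                 raw), call. = FALSE)
  }
  stem_canonical <- if (tolower(stem[2]) == "let") "let" else "miR"
  rest <- stem[3]

  # pearl-oyster style placeholder suffixes (-x/-y/-z) carry no arm identity
  rest <- sub("-[xyzXYZ]$", "", rest)

  arm <- "none"
  arm_m <- regmatches(rest, regexec("-(5[Pp]|3[Pp])$", rest))[[1]]
  if (length(arm_m) == 2L) {
    arm <- tolower(arm_m[2])
    rest <- sub("-(5[Pp]|3[Pp])$", "", rest)
  }

  if (!grepl("^-?[0-9]", rest)) {
    stop(sprintf("'%s' has no numeric miRNA identifier", raw), call. = FALSE)
  }
  list(base = paste0(stem_canonical, rest), arm = arm)
}

#' Canonicalize mature miRNA names
#'
#' Reduces heterogeneous study-reported names to a species-independent
#' mature identity: the species prefix is stripped, stem casing is
#' normalized (`MiR-x` -> `miR-x`, `Let-7a` -> `let-7a`), a `-5p`/`-3p` arm
#' suffix (case-insensitive) is split into its own field, underscore
#' annotations (`_1`, `_2`) and single-letter placeholder suffixes
#' (`-x`/`-y`/`-z`) are dropped. Armless names stay armless; no dominant-arm
#' guessing is performed.
#'
#' @param x Character vector of raw names.
#' @param prefixes Recognized species prefixes; see [mirna_prefixes()].
#' @return A tibble with one row per input: `raw`, `base` (e.g. `"miR-148a"`,
#'   `"let-7a"`), `arm` (`"5p"`, `"3p"` or `"none"`) and `display`
#'   (`base-arm`, or the bare base when armless). Parsing the display form
#'   again round-trips to the same identity.
#' @examples
#' canonicalize(c("Bta-let-7a-5p", "spu-miR-92b-3p", "miR-100-x"))
#' @export
canonicalize <- function(x, prefixes = mirna_prefixes()) {
  stopifnot(is.character(x))
  parsed <- lapply(x, parse_one_mirna, prefixes = prefixes)
  base <- vapply(parsed, `[[`, character(1), "base")
  arm <- vapply(parsed, `[[`, character(1), "arm")
  tibble::tibble(
    raw = x,
    base = base,
    arm = arm,
    display = mirna_display(base, arm)
  )
}

#' Build the display form of a canonical miRNA
#'
#' @param base Canonical base token(s), e.g. `"miR-148a"`.
#' @param arm Arm token(s): `"5p"`, `"3p"` or `"none"`.
#' @return `base-arm`, or `base` alone when `arm == "none"`.
#' @export
mirna_display <- function(base, arm) {
  ifelse(arm == "none", base, paste(base, arm, sep = "-"))
}

#' Canonical display names
#'
#' Convenience wrapper returning only the display form of [canonicalize()].
#'
#' @inheritParams canonicalize
#' @return Character vector of display-form canonical names.
#' @export
canonical_names <- function(x, prefixes = mirna_prefixes()) {
  canonicalize(x, prefixes = prefixes)$display
}

#' Compare two miRNA identities
#'
#' Under the `exact` policy two names match only with equal base and equal
#' arm. Under `lenient`, an armless record matches either arm of the same
#' base (useful when one study reports `miR-148a` and another
#' `miR-148a-3p`).
#'
#' @param a,b Raw or display-form names (length-1 character) or single-row
#'   results of [canonicalize()].
#' @param arm_policy `"exact"` (default) or `"lenient"`.
#' @return Logical scalar.
#' @export
same_mirna <- function(a, b, arm_policy = c("exact", "lenient")) {
  arm_policy <- match.arg(arm_policy)
  ca <- if (is.data.frame(a)) a else canonicalize(as.character(a))
  cb <- if (is.data.frame(b)) b else canonicalize(as.character(b))
  stopifnot(nrow(ca) == 1L, nrow(cb) == 1L)
  if (ca$base != cb$base) {
    return(FALSE)
  }
  if (arm_policy == "exact") {
    ca$arm == cb$arm
  } else {
    ca$arm == cb$arm || ca$arm == "none" || cb$arm == "none"
  }
}

#' Collapse a miRNA to its family key
#'
#' Optional coarser identity that removes the trailing paralog letter
#' (`miR-92a` and `miR-92b` -> `miR-92`). Never used by the reproduction
#' path, where lettered paralogs stay distinct.
#'
#' @param base Character vector of canonical base tokens.
#' @return Character vector of family keys.
#' @export
mirna_family <- function(base) {
  sub("(?<=[0-9])[a-z]$", "", base, perl = TRUE)
}

#' Read a conserved-miRNA allow-list
#'
#' Plain UTF-8 text, one display-form name per line; `#` starts a comment.
#'
#' @param path File path.
#' @return Sorted character vector of canonical display names.
#' @export
read_conserved_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("conserved allow-list is empty: ", path, call. = FALSE)
  }
  sort(unique(canonical_names(lines)))
}

#' Filter a name set down to conserved miRNAs
#'
#' Arm-exact intersection with an allow-list; order-independent.
#'
#' @param names Character vector of raw or display names.
#' @param allow Allow-list as returned by [read_conserved_list()] (or any
#'   character vector of names; canonicalized before matching).
#' @return Sorted character vector of the canonical display names kept.
#' @export
filter_conserved <- function(names, allow) {
  if (length(allow) == 0L) {
    stop("conserved allow-list must be non-empty", call. = FALSE)
  }
  keep <- canonical_names(names)
  allow <- canonical_names(allow)
  sort(unique(keep[keep %in% allow]))
}
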