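# Rule-based simulated proteolysis: ExPASy Peptide Cutter style specificity
# tables, complete digestion (every predicted site cut).

pat <- function(residues, invert = FALSE) list(residues = residues, invert = invert)

buildRules <- function() {
  basic <- c("H", "K", "R")
  # Common pepsin context constraints: no basic residue at P3, no proline at
  # P2 or P2'.
  pepsinCtx <- list(P3 = pat(basic, invert = TRUE), P2 = pat("P", invert = TRUE),
                    P2p = pat("P", invert = TRUE))
  pepsinBranches <- function(hydrophobic, aromaticExt) {
    br <- list(
      c(pepsinCtx, list(P1 = pat("R", invert = TRUE), P1p = pat(hydrophobic))),
      c(pepsinCtx, list(P1 = pat(c(hydrophobic, aromaticExt)))))
    if (length(aromaticExt))
      # pH > 2 extension: W/Y accepted at P1', but not after a basic residue
      # (calibrated against the published hemoglobin digest; see vignette).
      br <- append(br, list(c(pepsinCtx, list(P1 = pat(basic, invert = TRUE),
                                              P1p = pat(aromaticExt)))), 1L)
    br
  }
  list(
    trypsin = new("CleavageRule", name = "trypsin",
      specificity = list(list(P1 = pat(c("K", "R")), P1p = pat("P", invert = TRUE))),
      exceptions = list(
        list(action = "rescue", P2 = pat("W"), P1 = pat("K"), P1p = pat("P")),
        list(action = "rescue", P2 = pat("M"), P1 = pat("R"), P1p = pat("P")),
        list(action = "veto", P2 = pat(c("C", "D")), P1 = pat("K"), P1p = pat("D")),
        list(action = "veto", P2 = pat("C"), P1 = pat("K"), P1p = pat(c("H", "Y"))),
        list(action = "veto", P2 = pat("C"), P1 = pat("R"), P1p = pat("K")),
        list(action = "veto", P2 = pat("R"), P1 = pat("R"), P1p = pat(c("H", "R"))))),
    pepsin_ph1.3 = new("CleavageRule", name = "pepsin_ph1.3",
      specificity = pepsinBranches(c("F", "L"), character()),
      exceptions = list()),
    pepsin_ph_gt2 = new("CleavageRule", name = "pepsin_ph_gt2",
      specificity = pepsinBranches(c("F", "L"), c("W", "Y")),
      exceptions = list()))
}

ruleRegistry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildRules()
    cache
  }
})

#' Built-in protease cleavage rules
#'
#' \code{availableCleavageRules()} lists the bundled rule names;
#' \code{getCleavageRule()} retrieves one as a [CleavageRule-class].
#' \code{"trypsin"} follows the published high-specificity table (cut after
#' K/R unless proline follows, with the WKP/MRP rescues and the CKD, DKD, CKH,
#' CKY, CRK, RRH, RRR vetoes).  \code{"pepsin_ph1.3"} cuts bonds with F/L at
#' P1 or P1'; \code{"pepsin_ph_gt2"} additionally accepts W/Y, with the W/Y
#' P1' branch suppressed after a basic residue.  All pepsin branches require
#' no H/K/R at P3 and no proline at P2 or P2'.
#'
#' @param name one of \code{availableCleavageRules()}, or \code{"pepsin"}
#'   (alias for the pH > 2 variant used in the hemoglobin reproduction).
#' @return a [CleavageRule-class]
#' @examples
#' cleavageSites("AAKAA", getCleavageRule("trypsin"))
#' @export
getCleavageRule <- function(name) {
  if (identical(name, "pepsin")) name <- "pepsin_ph_gt2"
  reg <- ruleRegistry()
  if (!name %in% names(reg))
    stop("unknown cleavage rule '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[name]]
}

#' @rdname getCleavageRule
#' @export
availableCleavageRules <- function() names(ruleRegistry())

#' Parse FASTA records
#'
#' Accepts either a path to a FASTA file or FASTA text (a single string or a
#' character vector of lines).  Identifiers are taken from the header up to the
#' first whitespace; sequence bodies are upper-cased with whitespace and gap
#' characters stripped.  Reading is delegated to
#' \code{Biostrings::readAAStringSet}.
#'
#' @param input file path or FASTA text.
#' @return named character vector of sequences, in file order.
#' @export
parseFasta <- function(input) {
  if (!is.character(input) || !length(input))
    stop("input must be FASTA text or a file path", call. = FALSE)
  path <- input
  if (length(input) > 1L || grepl("\n", input) || startsWith(trimws(input[1]), ">")) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(input, "\n")), path)
  } else if (!file.exists(input)) {
    stop("input is neither FASTA text nor an existing file: ", input, call. = FALSE)
  }
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e),
                                           call. = FALSE))
  if (!length(set)) stop("FASTA input contains no records", call. = FALSE)
  seqs <- toupper(gsub("[-. *]", "", as.character(set)))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (any(!nzchar(seqs)))
    stop("FASTA record '", names(seqs)[!nzchar(seqs)][1], "' has an empty sequence",
         call. = FALSE)
  seqs
}

matchWindow <- function(res, k, pattern) {
  # res: residue vector; k: cut position (bond between res[k] and res[k+1]).
  offsets <- c(P4 = -3L, P3 = -2L, P2 = -1L, P1 = 0L, P1p = 1L, P2p = 2L)
  for (pos in setdiff(names(pattern), "action")) {
    idx <- k + offsets[[pos]]
    if (idx < 1L || idx > length(res)) return(FALSE)  # no residue matches nothing
    el <- pattern[[pos]]
    hit <- res[idx] %in% el$residues
    if (el$invert) hit <- !hit
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Predict cleavage sites
#'
#' Applies a [CleavageRule-class] to every internal peptide bond.  Position k
#' in the returned vector means the bond between residues k and k+1 is cut
#' (1 <= k <= nchar(sequence) - 1).
#'
#' @param sequence protein sequence (canonical one-letter codes).
#' @param rule a [CleavageRule-class] or a rule name accepted by
#'   [getCleavageRule()].
#' @return strictly increasing integer vector of cut positions.
#' @export
cleavageSites <- function(sequence, rule) {
  if (is.character(rule)) rule <- getCleavageRule(rule)
  stopifnot(is(rule, "CleavageRule"))
  res <- checkSequence(sequence)
  n <- length(res)
  if (n < 2L) return(integer())
  cut <- logical(n - 1L)
  for (k in seq_len(n - 1L)) {
    base <- any(vapply(rule@specificity, function(p) matchWindow(res, k, p), TRUE))
    veto <- rescue <- FALSE
    for (ex in rule@exceptions) {
      if (matchWindow(res, k, ex)) {
        if (ex$action == "veto") veto <- TRUE else rescue <- TRUE
      }
    }
    cut[k] <- (base && !veto) || rescue
  }
  which(cut)
}

#' Digest a protein sequence
#'
#' Complete digestion: every predicted site is cut, and the fragments are the
#' maximal substrings between consecutive cut positions (plus the termini).
#' Fragment coordinates are 0-based half-open internally; the returned table
#' reports 1-based inclusive \code{start}/\code{end}.
#'
#' @inheritParams cleavageSites
#' @param parentId identifier recorded with each fragment.
#' @return data.frame with columns \code{parent_id}, \code{protease},
#'   \code{start}, \code{end}, \code{length}, \code{sequence}; fragments are
#'   non-overlapping and tile the parent exactly.
#' @examples
#' digestSequence("AAKAA", "trypsin")
#' @export
digestSequence <- function(sequence, rule, parentId = "protein") {
  if (is.character(rule)) rule <- getCleavageRule(rule)
  sites <- cleavageSites(sequence, rule)
  n <- nchar(sequence)
  bounds <- c(0L, sites, n)
  starts <- head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  data.frame(parent_id = parentId, protease = rule@name,
             start = starts, end = ends, length = ends - starts + 1L,
             sequence = substring(sequence, starts, ends),
             stringsAsFactors = FALSE)
}

#' Enumerate pentapeptide fragments across proteins and proteases
#'
#' Each protease is applied independently (no sequential double digestion);
#' fragments of the requested length are collected and deduplicated by
#' (sequence, protease, parent), keeping a stable order by parent then start.
#'
#' @param proteins named character vector of protein sequences.
#' @param rules list of [CleavageRule-class] objects or rule names.
#' @param length fragment length to keep (default 5).
#' @return data.frame with columns \code{sequence}, \code{protease},
#'   \code{parent_id}, \code{start}, \code{end}.
#' @examples
#' enumeratePentapeptides(hemoglobinSubunits(), list("pepsin", "trypsin"))
#' @export
enumeratePentapeptides <- function(proteins, rules, length = 5L) {
  if (!length(proteins)) {
    return(data.frame(sequence = character(), protease = character(),
                      parent_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
    stop("proteins must be a named character vector", call. = FALSE)
  if (!is.list(rules)) rules <- list(rules)
  frags <- list()
  for (rule in rules) {
    for (id in names(proteins)) {
      d <- digestSequence(proteins[[id]], rule, parentId = id)
      frags[[base::length(frags) + 1L]] <- d[d$length == length, , drop = FALSE]
    }
  }
  all <- do.call(rbind, frags)
  all <- all[order(all$parent_id, all$start), , drop = FALSE]
  all <- all[!duplicated(all[c("sequence", "protease", "parent_id")]), , drop = FALSE]
  rownames(all) <- NULL
  all[c("sequence", "protease", "parent_id", "start", "end")]
}
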