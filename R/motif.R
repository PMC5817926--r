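# Substrate-recognition sequence scanners: the 7-position Hsp40/DnaJ
# consensus motif and a heuristic DnaK hydrophobic-patch score.

.AA20 <- "ACDEFGHIKLMNPQRSTVWY"

# Position rules of the DnaJ consensus G X [LMQ] {P} X {P} {CIMPVW}.
# Wildcard positions admit only the 20 standard residues, so ambiguity
# codes (X, B, Z, J, U, O) fail every position -- a conservative choice.
.dnaj_regex <- function() {
  any20 <- paste0("[", .AA20, "]")
  notP <- paste0("[", gsub("P", "", .AA20), "]")
  not7 <- paste0("[", gsub("[CIMPVW]", "", .AA20), "]")
  paste0("(?=(G", any20, "[LMQ]", notP, any20, notP, not7, "))")
}

#' Scan a protein sequence for the Hsp40/DnaJ consensus motif
#'
#' Finds every (possibly overlapping) 7-mer matching the consensus
#' G X [LMQ] {P} X {P} {CIMPVW}, where X is any standard residue,
#' square brackets list allowed residues and braces list excluded ones.
#' Positions are 1-based inclusive; \code{offset} maps them into a parent
#' numbering (e.g. a fragment cut from a longer protein).
#'
#' @param sequence amino-acid string (one-letter codes). Ambiguity codes
#'   (B, J, O, U, X, Z) are tolerated but match no motif position;
#'   any other character is an error.
#' @param offset number of the first residue in the parent numbering
#'   (default 1).
#' @param id sequence identifier carried into the result.
#' @return data.frame with columns \code{seq_id}, \code{start},
#'   \code{end}, \code{match} (positions in parent numbering).
#' @examples
#' scan_dnaj_consensus("FAGKQLEDGRT", offset = 45)  # GKQLEDG at 47-53
#' @export
scan_dnaj_consensus <- function(sequence, offset = 1, id = "seq") {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), strsplit(paste0(.AA20, "BJOUXZ"), "")[[1]])
  if (length(bad))
    stop("invalid residue characters: ", paste(bad, collapse = ", "))
  hits <- gregexpr(.dnaj_regex(), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), match = character(0)))
  starts <- as.integer(hits)
  data.frame(seq_id = id,
             start = starts + offset - 1L,
             end = starts + offset + 5L,
             match = substring(sequence, starts, starts + 6L))
}

#' Scan sequences in a FASTA file for the DnaJ consensus
#'
#' @param path FASTA file of protein sequences.
#' @param offset numbering offset applied to every sequence.
#' @return row-bound match table over all sequences.
#' @export
scan_dnaj_fasta <- function(path, offset = 1) {
  seqs <- read_fasta_aa(path)
  do.call(rbind, lapply(names(seqs), function(id)
    scan_dnaj_consensus(seqs[[id]], offset = offset, id = id)))
}

# Kyte-Doolittle hydropathy scale.
.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Sliding-window hydrophobic-patch scores (DnaK-style heuristic)
#'
#' DnaK targets roughly five-residue hydrophobic patches, typically
#' containing leucine or isoleucine. This scanner reports, per window
#' position, the mean hydropathy (Kyte-Doolittle by default) and calls a
#' window a candidate patch when its mean score plus a small bonus per
#' contained Leu/Ile reaches a threshold. It is an explicitly heuristic
#' proxy for DnaK-site prediction, not a binding-energy model.
#'
#' @param sequence amino-acid string (standard 20 residues).
#' @param window window length (default 5); must not exceed the sequence.
#' @param scale named hydropathy scale; default Kyte-Doolittle.
#' @param threshold patch-calling threshold on the bonus-adjusted score.
#' @param li_bonus score bonus per Leu/Ile in the window (divided by the
#'   window length).
#' @return data.frame with \code{start}, \code{end}, \code{window},
#'   \code{score} (plain mean hydropathy), \code{n_LI} and \code{patch}.
#' @examples
#' scan_dnak_patches(strrep("L", 8))$patch  # every window is a patch
#' @export
scan_dnak_patches <- function(sequence, window = 5, scale = .KD_SCALE,
                              threshold = 2, li_bonus = 1) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (window < 1) stop("window must be >= 1")
  if (window > length(chars)) stop("window longer than the sequence")
  bad <- setdiff(unique(chars), names(scale))
  if (length(bad))
    stop("residues without a hydropathy value: ", paste(bad, collapse = ", "))
  h <- unname(scale[chars])
  cs <- c(0, cumsum(h))
  n <- length(chars) - window + 1L
  starts <- seq_len(n)
  score <- (cs[starts + window] - cs[starts]) / window
  isLI <- as.numeric(chars %in% c("L", "I"))
  csl <- c(0, cumsum(isLI))
  n_LI <- csl[starts + window] - csl[starts]
  adj <- score + li_bonus * n_LI / window
  data.frame(start = starts, end = starts + window - 1L,
             window = substring(sequence, starts, starts + window - 1L),
             score = score, n_LI = as.integer(n_LI),
             patch = adj >= threshold)
}
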