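# Experimental preference statistics from phage-display selections.
#
# Selected CDR window sequences (5-residue NNK-randomized windows) are
# counted per position; the preference W_ji is a Bayesian pseudo-counted
# log-odds of the observed amino-acid frequency against the NNK
# degenerate-codon background, in half-bit units:
#   W_ji = 2 log2( ((C_ji + sqrt(M) p_i) / (M + sqrt(M))) / p_i )
# deltaW_ji = 1 exactly when W_ji >= 0, i.e. when the observed count is at
# least the anticipated NNK frequency M p_i.

#' NNK degenerate-codon background amino-acid probabilities
#'
#' Enumerates the 32 NNK codons (N = A/C/G/T, K = G/T) against the standard
#' genetic code. The single amber stop (TAG) is handled by policy:
#' \code{"amber_to_Gln"} reads TAG as Gln (supE suppressor phage hosts),
#' \code{"renormalize_over_20"} drops it and renormalizes over the 20
#' amino acids.
#'
#' @param stop_policy stop-codon policy.
#' @return Named probability vector over the 20 one-letter codes, summing
#'   to 1.
#' @export
nnk_background <- function(stop_policy = c("amber_to_Gln",
                                           "renormalize_over_20")) {
  stop_policy <- match.arg(stop_policy)
  n <- c("A", "C", "G", "T")
  k <- c("G", "T")
  codons <- as.vector(outer(as.vector(outer(n, n, paste0)), k, paste0))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (stop_policy == "amber_to_Gln") {
    aa[codons == "TAG"] <- "Q"
    counts <- table(factor(aa, levels = AA1))
    p <- as.numeric(counts) / 32
  } else {
    aa <- aa[aa != "*"]
    counts <- table(factor(aa, levels = AA1))
    p <- as.numeric(counts) / sum(counts)
  }
  names(p) <- AA1
  p
}

#' Read selection sequences from FASTA or two-column TSV
#'
#' @param path input file. TSV columns: \code{library_id},
#'   \code{sequence}.
#' @param format \code{"fasta"} or \code{"tsv"}; guessed from the
#'   extension by default.
#' @return data.frame with columns \code{library_id}, \code{sequence}.
#' @export
read_selection_sequences <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    data.frame(library_id = names(ss), sequence = as.character(ss),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
}

#' Count amino acids per window position
#'
#' @param sequences character vector of equal-length amino-acid strings
#'   (duplicates counted as given).
#' @param positions optional position labels (default \code{pos1..k}).
#' @return list with \code{C} (positions x 20 count matrix) and \code{M}
#'   (sequences covering each position).
#' @export
count_profile <- function(sequences, positions = NULL) {
  stopifnot(length(sequences) >= 1L)
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  bad <- which(matrix(!(mat %in% AA1), nrow(mat)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid amino-acid character '%s' in sequence %d",
                 mat[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L]))
  if (is.null(positions)) positions <- paste0("pos", seq_len(w))
  stopifnot(length(positions) == w)
  C <- t(apply(mat, 2L, function(col) table(factor(col, levels = AA1))))
  dimnames(C) <- list(positions, AA1)
  list(C = C, M = stats::setNames(rep(length(sequences), w), positions))
}

#' Experimental preference W and its binary label
#'
#' @param C counts (positions x 20 matrix, or vector for one position).
#' @param M sequence count per position (scalar or per-row vector).
#' @param p NNK background probabilities.
#' @return list with matrices \code{W} (half-bits) and \code{deltaW}
#'   (0/1; 1 iff W >= 0).
#' @export
experimental_preference <- function(C, M, p = nnk_background()) {
  C <- rbind(C)
  if (is.null(colnames(C))) colnames(C) <- AA1
  if (!is.null(names(p))) p <- p[colnames(C)]
  stopifnot(all(p > 0), all(M >= 1))
  if (length(M) == 1L) M <- rep(M, nrow(C))
  q <- (C + outer(sqrt(M), p)) / (M + sqrt(M))
  W <- 2 * log2(sweep(q, 2L, p, "/"))
  list(W = W, deltaW = (W >= 0) * 1L)
}

#' Per-position information content of a selection profile
#'
#' Relative entropy (bits) of the pseudo-counted position frequencies
#' against the NNK background:
#' I_j = sum_i q_ji log2(q_ji / p_i), q_ji = (C_ji + sqrt(M) p_i) /
#' (M + sqrt(M)). Non-negative by Gibbs' inequality.
#'
#' @inheritParams experimental_preference
#' @return Numeric vector of I_j per position.
#' @export
information_content <- function(C, M, p = nnk_background()) {
  C <- rbind(C)
  if (is.null(colnames(C))) colnames(C) <- AA1
  if (!is.null(names(p))) p <- p[colnames(C)]
  if (length(M) == 1L) M <- rep(M, nrow(C))
  q <- (C + outer(sqrt(M), p)) / (M + sqrt(M))
  rowSums(q * log2(sweep(q, 2L, p, "/")))
}

#' Full preference profile of a selection dataset
#'
#' Convenience wrapper: counts, W, deltaW and information content in one
#' long-format table suitable for LOGO export and model training.
#'
#' @param sequences equal-length selection window sequences.
#' @param positions position labels (e.g. \code{"28-L"}).
#' @param p NNK background.
#' @return A \code{preference_profile}: long data.frame (position, aa, C,
#'   W, deltaW, I) with the count matrix, M and background as attributes.
#' @export
preference_profile <- function(sequences, positions = NULL,
                               p = nnk_background()) {
  cp <- count_profile(sequences, positions)
  ep <- experimental_preference(cp$C, cp$M, p)
  info <- information_content(cp$C, cp$M, p)
  long <- data.frame(
    position = rep(rownames(cp$C), times = ncol(cp$C)),
    aa = rep(colnames(cp$C), each = nrow(cp$C)),
    C = as.vector(cp$C), W = as.vector(ep$W), deltaW = as.vector(ep$deltaW),
    I = rep(info, times = ncol(cp$C)), stringsAsFactors = FALSE)
  long <- long[order(long$position, long$aa), ]
  rownames(long) <- NULL
  class(long) <- c("preference_profile", class(long))
  attr(long, "C") <- cp$C
  attr(long, "M") <- cp$M
  attr(long, "background") <- p
  long
}

#' Write a preference/LOGO table as TSV
#'
#' @param x a \code{preference_profile}.
#' @param path output file.
#' @export
write_profile_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
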