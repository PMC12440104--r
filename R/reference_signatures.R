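#' Synthetic reference SBS signature catalog
#'
#' Constructs a small catalog of four synthetic single-base-substitution
#' signature profiles whose qualitative shapes mimic well-known signature
#' families: a clock-like CpG deamination profile (mass on N[C>T]G
#' channels), a flat "featureless" profile, an oxidative-damage-like
#' profile (C>A dominated), and a T>A-dominated profile. These are
#' synthetic stand-ins constructed for testing and demonstration; they
#' are not the published COSMIC vectors. Users analysing real cohorts
#' should supply their own reference TSV via
#' \code{\link{read_reference_signatures}}.
#'
#' @return A 96 x 4 matrix of probability vectors (columns sum to 1) with
#'   rownames \code{sbs_channels()} and colnames
#'   \code{c("SBS1_like", "SBS5_like", "SBS18_like", "SBS34_like")}.
#' @export
synthetic_reference_signatures <- function() {
  ch <- sbs_channels()
  sub_class <- substr(ch, 3, 5)
  flank3 <- substr(ch, 7, 7)
  flank5 <- substr(ch, 1, 1)

  # clock-like: C>T at CpG dinucleotides dominates
  sig1 <- ifelse(sub_class == "C>T" & flank3 == "G", 20,
                 ifelse(sub_class == "C>T", 1.5, 0.15))

  # featureless: near-uniform with a mild T>C tilt
  sig5 <- ifelse(sub_class == "T>C", 1.6, 1)

  # oxidative-damage-like: C>A dominated, strongest with 5' flank G/T
  sig18 <- ifelse(sub_class == "C>A" & flank5 %in% c("G", "T"), 12,
                  ifelse(sub_class == "C>A", 6, 0.2))

  # T>A dominated at A/T homopolymer-like flanks
  sig34 <- ifelse(sub_class == "T>A" & flank5 %in% c("A", "T"), 14,
                  ifelse(sub_class == "T>A", 4, 0.15))

  m <- cbind(SBS1_like = sig1, SBS5_like = sig5,
             SBS18_like = sig18, SBS34_like = sig34)
  rownames(m) <- ch
  sweep(m, 2, colSums(m), "/")
}

#' Read a reference signature catalog from TSV
#'
#' Expects a tab-separated file with a \code{channel} column holding the
#' 96 context labels followed by one column per signature. Channels must
#' be exactly the standard 96-channel set; rows are reordered to the
#' canonical order and columns renormalized to probability vectors.
#'
#' @param path path to the TSV file.
#' @return A 96 x K probability matrix with channel rownames.
#' @export
read_reference_signatures <- function(path) {
  if (!file.exists(path)) stop("reference signature file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"channel" %in% names(df)) {
    stop("reference signature file lacks required column: channel")
  }
  ch <- sbs_channels()
  if (!setequal(df$channel, ch) || nrow(df) != 96) {
    stop("reference signature channels do not match the 96-channel set")
  }
  m <- as.matrix(df[match(ch, df$channel), setdiff(names(df), "channel"),
                    drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("reference signatures must be finite and non-negative")
  }
  rownames(m) <- ch
  sweep(m, 2, colSums(m), "/")
}

#' Write a reference signature catalog to TSV
#'
#' @param signatures 96 x K matrix with channel rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_reference_signatures <- function(signatures, path) {
  df <- data.frame(channel = rownames(signatures), signatures,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
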