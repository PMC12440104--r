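#' The 96 single-base-substitution context channels
#'
#' Channel labels follow the standard COSMIC ordering: the six
#' pyrimidine-centric substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
#' in order, and within each class the sixteen flank pairs with the 5'
#' flank varying slowest, both flanks alphabetical (A, C, G, T). Labels
#' look like \code{"A[C>A]A"}.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(f5) {
      paste0(f5, "[", s, "]", bases)
    }))
  }), use.names = FALSE)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Complement of single DNA bases
#'
#' @param x character vector of single bases (A/C/G/T).
#' @return Complemented bases; non-ACGT input raises an error.
#' @keywords internal
complement_base <- function(x) {
  bad <- !is.na(x) & !x %in% names(.COMPLEMENT)
  if (any(bad)) {
    stop("non-ACGT base encountered: ", paste(unique(x[bad]), collapse = ", "))
  }
  out <- unname(.COMPLEMENT[x])
  out[is.na(x)] <- NA_character_
  out
}

#' Map an SNV with flanking bases to its 96-context channel
#'
#' Purine-reference SNVs (ref A or G) are reverse-complemented onto the
#' pyrimidine-centric channel: ref, alt and both flanks are complemented
#' and the flanks are swapped.
#'
#' @param ref,alt single reference/alternate bases.
#' @param context5,context3 single bases immediately 5' and 3' of the
#'   variant on the reported strand. Missing context yields \code{NA}.
#' @return Character vector of channel labels (NA where context missing).
#' @export
snv_channel <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  context5 <- toupper(context5); context3 <- toupper(context3)
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context5) & !is.na(context3)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; f5 <- context5[ok]; f3 <- context3[ok]
  complement_base(r); complement_base(a)  # validate bases early
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    newf5 <- complement_base(f3[pur])
    newf3 <- complement_base(f5[pur])
    r[pur] <- complement_base(r[pur])
    a[pur] <- complement_base(a[pur])
    f5[pur] <- newf5
    f3[pur] <- newf3
  }
  complement_base(f5); complement_base(f3)
  lab <- paste0(f5, "[", r, ">", a, "]", f3)
  lab[!lab %in% sbs_channels()] <- NA_character_
  out[ok] <- lab
  out
}
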