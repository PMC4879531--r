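#' Restriction enzyme definitions
#'
#' A GBS enzyme is described by its recognition motif, the offset of the
#' top-strand cut within the motif, and the cut-site remnant expected at the
#' start of every demultiplexed read (immediately after the inline barcode).
#' Only palindromic recognition sites are supported, which covers the
#' 6-cutter/8-cutter pair classically screened for chicken GBS libraries
#' (PstI, CTGCA^G, and SbfI, CCTGCA^GG).
#'
#' The remnant convention follows the GBS literature: for PstI the expected
#' read prefix is \code{CTGCA}. Note this is the 5' five bases of the motif;
#' the sticky-end chemistry would suggest \code{TGCAG}, and both can be used
#' by constructing an enzyme with a custom \code{remnant}.
#'
#' @param name enzyme name; \code{gbs_enzyme()} looks up the built-in table
#'   (\code{"PstI"}, \code{"SbfI"}) unless \code{recognition} is supplied.
#' @param recognition uppercase ACGT recognition motif (palindromic).
#' @param cut_offset integer, bases from motif start to the top-strand cut.
#' @param remnant read prefix expected after the barcode; defaults to the
#'   motif truncated at the cut.
#' @return an object of class \code{gbs_enzyme}.
#' @examples
#' gbs_enzyme("PstI")
#' gbs_enzyme("EcoRV-like", recognition = "GATATC", cut_offset = 3)
#' @export
gbs_enzyme <- function(name, recognition = NULL, cut_offset = NULL,
                       remnant = NULL) {
  if (methods::is(name, "gbs_enzyme")) return(name)
  builtin <- list(
    PstI = list(recognition = "CTGCAG",  cut_offset = 5L, remnant = "CTGCA"),
    SbfI = list(recognition = "CCTGCAGG", cut_offset = 6L, remnant = "CCTGCA"))
  if (is.null(recognition)) {
    assert_that(name %in% names(builtin),
                "unknown enzyme '%s'; built-ins: %s", name,
                paste(names(builtin), collapse = ", "))
    b <- builtin[[name]]
    recognition <- b$recognition
    cut_offset <- b$cut_offset
    remnant <- remnant %||% b$remnant
  }
  recognition <- toupper(recognition)
  assert_that(nzchar(recognition) && grepl("^[ACGT]+$", recognition),
              "recognition motif must be non-empty uppercase ACGT")
  assert_that(is_palindrome(recognition),
              "unsupported enzyme '%s': recognition site %s is not palindromic",
              name, recognition)
  cut_offset <- as.integer(cut_offset %||% nchar(recognition))
  assert_that(cut_offset >= 0L && cut_offset <= nchar(recognition),
              "cut_offset must lie within the recognition motif")
  remnant <- toupper(remnant %||% substr(recognition, 1L, cut_offset))
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset, remnant = remnant),
            class = "gbs_enzyme")
}

#' @export
print.gbs_enzyme <- function(x, ...) {
  cat(sprintf("<gbs_enzyme> %s  %s^%s  remnant=%s\n", x$name,
              substr(x$recognition, 1, x$cut_offset),
              substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)),
              x$remnant))
  invisible(x)
}
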