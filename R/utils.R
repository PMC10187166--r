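# Internal helpers shared across parsers and the harvester.

#' @noRd
read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    raw <- readBin(x, "raw", n = file.size(x))
    txt <- rawToChar(raw)
    enc <- validEnc(txt)
    if (!enc) txt <- iconv(rawToChar(raw), from = "latin1", to = "UTF-8")
    x <- txt
  }
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    # accept both LF and CRLF
    x <- strsplit(gsub("\r\n", "\n", x, fixed = TRUE), "\n", fixed = TRUE)[[1L]]
  }
  sub("\r$", "", x)
}

#' Extract the lowercase extension of a file name
#'
#' Text after the final dot, lowercased. Names ending in `.tar.gz` map to
#' `"gz"` (the archive-ness is visible from the name itself); dotless names
#' map to `"none"` so that extension tallies have an explicit bucket for
#' extension-less files.
#'
#' @param name character vector of file names (paths allowed).
#' @return character vector of lowercase extension tokens, `"none"` when the
#'   name has no dot.
#' @examples
#' file_extension(c("traj.XTC", "README", "archive.tar.gz"))
#' @export
file_extension <- function(name) {
  base <- basename(name)
  ext <- tolower(tools::file_ext(base))
  ifelse(nzchar(ext), ext, "none")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-away-from-zero to nearest integer (base round() is banker's)
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @noRd
as_scalar_chr <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[1L])) NA_character_ else as.character(x[1L])
}

# deterministic local RNG: run code under a seed without touching the
# caller's .Random.seed (generators must be pure functions of their spec)
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
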