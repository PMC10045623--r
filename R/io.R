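#' Read and write plain-text PGM (P2) images
#'
#' Plain PGM keeps the whole artifact text-only and needs no external
#' imaging library; intensities are 8-bit (`maxval` 255).
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param path File path.
#' @param comment Optional comment string embedded in the header
#'   (provenance).
#' @return `path` invisibly (write); the image matrix (read).
#' @export
write_pgm <- function(img, path, comment = NULL) {
  assert_gray(img)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P2", con)
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf("%d %d", ncol(img), nrow(img)), con)
  writeLines("255", con)
  # row-major pixel dump, one image row per line
  writeLines(apply(img, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (trimws(lines[1]) != "P2") stop("not a plain (P2) PGM file")
  tokens <- as.integer(unlist(strsplit(paste(lines[-1], collapse = " "),
                                       "[[:space:]]+")))
  tokens <- tokens[!is.na(tokens)]
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)]
  if (length(px) != w * h) stop("corrupt PGM: pixel count mismatch")
  img <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  if (maxval != 255) img <- matrix(as.integer(round(img * 255 / maxval)), h, w)
  img
}

#' Provenance hash of an R object
#'
#' A small polynomial string hash (mod 2^31 - 1) of the object's
#' canonical JSON form, used to tag every pipeline artifact with the
#' configuration that produced it. A tag, not a cryptographic digest.
#'
#' @param x Any jsonlite-serializable object.
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  bytes <- utf8ToInt(s)
  h <- 7
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}
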