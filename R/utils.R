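# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a sub-seed from a master seed; stays below 2^31
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

#' Atomic file write: write to a temp file in the same directory, then rename
#' @noRd
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

#' Validate a DNA sequence over {A,C,G,T,N}; returns the uppercased string
#' @noRd
check_dna <- function(seq, id) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'")
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "", fixed = TRUE)[[1]])
    stop("record '", id, "' contains non-{A,C,G,T,N} characters: ",
         paste(bad, collapse = ""))
  }
  seq
}

#' One-row reference data frame (id, seq, taxon)
#' @noRd
ref_df <- function(id, seq, taxon = NA_character_) {
  data.frame(id = id, seq = seq, taxon = taxon, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
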