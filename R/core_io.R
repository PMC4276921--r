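# Readers and writers for the external formats the toolkit touches.
#
# Internal coordinate convention: 0-based, half-open everywhere. Conversion to
# the 1-based conventions of SAM and the tabular outputs happens only at the
# I/O boundary in this file.

#' Construct an alignment record
#'
#' The toolkit-internal, CIGAR-free representation of one read-to-reference
#' alignment: a matrix of aligned (read offset, reference offset) pairs, both
#' 0-based. A deletion relative to the reference is a pair with `NA` in the
#' read column; an insertion is a pair with `NA` in the reference column.
#'
#' @param read_id,ref_id record identifiers.
#' @param ref_start 0-based leftmost aligned reference position.
#' @param pairs two-column integer matrix (`read`, `ref`) of aligned offsets.
#' @param strand `"+"` or `"-"` (the internal mapper only emits `"+"`).
#' @param identity fraction of matching aligned bases in `[0, 1]`, computed
#'   over non-N aligned pairs.
#' @return an object of class `ngs_alignment`.
#' @export
alignment_record <- function(read_id, ref_id, ref_start, pairs,
                             strand = "+", identity = NA_real_) {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  if (ref_start < 0L) stop("ref_start must be >= 0")
  if (!is.na(identity) && (identity < 0 || identity > 1)) {
    stop("identity must lie in [0, 1]")
  }
  refs <- pairs[, 2L]
  refs <- refs[!is.na(refs)]
  if (is.unsorted(refs, strictly = TRUE)) {
    stop("aligned reference offsets must be strictly increasing")
  }
  structure(
    list(read_id = read_id, ref_id = ref_id,
         ref_start = as.integer(ref_start),
         pairs = matrix(as.integer(pairs), ncol = 2L,
                        dimnames = list(NULL, c("read", "ref"))),
         strand = strand, identity = identity),
    class = "ngs_alignment")
}

#' Read a FASTA file
#'
#' Sequences are uppercased; characters outside `{A,C,G,T,N}` raise an error
#' naming the offending record.
#'
#' @param path FASTA file.
#' @return data frame with columns `id`, `seq`, `taxon` (`NA`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) check_dna(seqs[[i]], ids[[i]]),
                 character(1))
  data.frame(id = ids, seq = unname(seqs), taxon = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data frame with `id` and `seq` columns, or a named character
#'   vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.data.frame(x)) x <- stats::setNames(x$seq, x$id)
  set <- Biostrings::BStringSet(x)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  Biostrings::writeXStringSet(set, tmp, format = "fasta", width = width)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

#' Read a FASTQ file (4-line-per-record dialect)
#'
#' @param path FASTQ file.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) | seq_along(lines) %% 4L != 0L]
  if (length(lines) == 0L) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ file is not 4-line-per-record: ", path)
  }
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(heads, "@"))) stop("malformed FASTQ header in ", path)
  ids <- sub("\\s.*$", "", substring(heads, 2L))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop("record '", ids[bad[1L]],
         "': sequence and quality strings differ in length")
  }
  for (i in seq_along(ids)) check_dna(seqs[[i]], ids[[i]])
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' Reads without qualities are written with a constant `"I"` quality string.
#'
#' @param reads data frame with `id`, `seq`, optional `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else NA_character_
  qual <- ifelse(is.na(qual),
                 vapply(nchar(reads$seq),
                        function(n) strrep("I", n), character(1)),
                 qual)
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  write_atomic(lines, path)
}

# CIGAR string -> per-op (op, len) matrix; restricted dialect
parse_cigar <- function(cigar) {
  if (cigar == "*") stop("missing CIGAR not supported")
  ops <- strsplit(gsub("[0-9]", "", cigar), "")[[1]]
  bad <- setdiff(ops, c("M", "=", "X", "I", "D", "S"))
  if (length(bad) > 0L) {
    stop("unsupported CIGAR operation '", bad[1L], "' in ", cigar)
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  cbind(op = ops, len = lens)
}

#' Read alignments from a SAM file (minimal dialect)
#'
#' Supports the mandatory columns with CIGAR operations `M/=/X/I/D/S`.
#' Unmapped records (flag bit 4) are skipped. SAM's 1-based `POS` is
#' converted to the toolkit's 0-based convention. Identity is taken from an
#' `XI:f:` tag when present, otherwise recomputed from `SEQ` against the
#' reference (N bases excluded from the denominator).
#'
#' @param path SAM file.
#' @param refs reference data frame as returned by [read_fasta()].
#' @return list of [alignment_record()] objects.
#' @export
read_sam <- function(path, refs) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  ref_seqs <- stats::setNames(refs$seq, refs$id)
  out <- vector("list", length(lines))
  n <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) != 0L) next
    rname <- f[3L]
    if (!rname %in% names(ref_seqs)) {
      stop("SAM RNAME '", rname, "' not present in the reference set")
    }
    pos0 <- as.integer(f[4L]) - 1L
    cig <- parse_cigar(f[6L])
    seq <- toupper(f[10L])
    ro <- 0L; fo <- pos0
    pr <- list(); pf <- list()
    for (i in seq_len(nrow(cig))) {
      op <- cig[i, "op"]; len <- as.integer(cig[i, "len"])
      if (op %in% c("M", "=", "X")) {
        pr[[length(pr) + 1L]] <- ro + seq_len(len) - 1L
        pf[[length(pf) + 1L]] <- fo + seq_len(len) - 1L
        ro <- ro + len; fo <- fo + len
      } else if (op == "I") {
        pr[[length(pr) + 1L]] <- ro + seq_len(len) - 1L
        pf[[length(pf) + 1L]] <- rep(NA_integer_, len)
        ro <- ro + len
      } else if (op == "D") {
        pr[[length(pr) + 1L]] <- rep(NA_integer_, len)
        pf[[length(pf) + 1L]] <- fo + seq_len(len) - 1L
        fo <- fo + len
      } else if (op == "S") {
        ro <- ro + len
      }
    }
    pairs <- cbind(read = unlist(pr), ref = unlist(pf))
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    xi <- regmatches(ln, regexpr("XI:f:[0-9.eE+-]+", ln))
    if (length(xi) == 1L) {
      identity <- as.numeric(sub("XI:f:", "", xi))
    } else {
      identity <- alignment_identity(pairs, seq, ref_seqs[[rname]])
    }
    ref_first <- pairs[!is.na(pairs[, "ref"]), "ref"][1L]
    n <- n + 1L
    out[[n]] <- alignment_record(f[1L], rname, ref_first, pairs,
                                 strand, identity)
  }
  out[seq_len(n)]
}

# positionwise match fraction over aligned non-N pairs
alignment_identity <- function(pairs, read_seq, ref_seq) {
  ok <- !is.na(pairs[, 1L]) & !is.na(pairs[, 2L])
  rb <- strsplit(read_seq, "", fixed = TRUE)[[1]][pairs[ok, 1L] + 1L]
  fb <- strsplit(ref_seq, "", fixed = TRUE)[[1]][pairs[ok, 2L] + 1L]
  keep <- rb != "N" & fb != "N"
  if (sum(keep) == 0L) return(0)
  mean(rb[keep] == fb[keep])
}

# pairs matrix -> CIGAR, given total read length (adds soft clips at ends)
pairs_to_cigar <- function(pairs, read_len) {
  ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    if (len == 0L) return()
    k <- length(ops)
    if (k > 0L && ops[k] == op) {
      lens[k] <<- lens[k] + len
    } else {
      ops[k + 1L] <<- op; lens[k + 1L] <<- len
    }
  }
  aligned_reads <- pairs[, 1L]
  first_read <- suppressWarnings(min(aligned_reads, na.rm = TRUE))
  last_read <- suppressWarnings(max(aligned_reads, na.rm = TRUE))
  push("S", first_read)
  for (i in seq_len(nrow(pairs))) {
    r <- pairs[i, 1L]; f <- pairs[i, 2L]
    if (!is.na(r) && !is.na(f)) push("M", 1L)
    else if (is.na(f)) push("I", 1L)
    else push("D", 1L)
  }
  push("S", read_len - last_read - 1L)
  paste0(lens, ops, collapse = "")
}

#' Write alignments to SAM
#'
#' @param alignments list of [alignment_record()] objects.
#' @param reads read data frame (for `SEQ`/`QUAL` columns).
#' @param refs reference data frame (for `@SQ` headers).
#' @param path output file.
#' @export
write_sam <- function(alignments, reads, refs, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", refs$id, "\tLN:", nchar(refs$seq)))
  seq_map <- stats::setNames(reads$seq, reads$id)
  qual_map <- if ("qual" %in% names(reads)) {
    stats::setNames(reads$qual, reads$id)
  } else {
    stats::setNames(rep(NA_character_, nrow(reads)), reads$id)
  }
  body <- vapply(alignments, function(a) {
    seq <- seq_map[[a$read_id]]
    qual <- qual_map[[a$read_id]]
    if (is.na(qual)) qual <- "*"
    flag <- if (a$strand == "-") 16L else 0L
    paste(a$read_id, flag, a$ref_id, a$ref_start + 1L, 255L,
          pairs_to_cigar(a$pairs, nchar(seq)), "*", 0L, 0L, seq, qual,
          sprintf("XI:f:%.10g", a$identity), sep = "\t")
  }, character(1))
  write_atomic(c(header, body), path)
}

#' Serialize a tree to Newick
#'
#' Trees are nested lists: leaves are `list(label =, branch =)`, internal
#' nodes `list(children = list(...), branch =)`. Labels containing Newick
#' metacharacters or whitespace are single-quoted.
#'
#' @param tree tree node (usually from [hierarchical_cluster()]).
#' @return a Newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  fmt_len <- function(x) {
    if (is.null(x) || is.na(x)) return("")
    if (x < 0) stop("negative branch length in tree")
    s <- if (x == round(x)) sprintf("%.1f", x) else sprintf("%.10g", x)
    paste0(":", s)
  }
  quote_label <- function(lab) {
    if (grepl("[][(){};:,' \t]", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else {
      lab
    }
  }
  walk <- function(node) {
    if (!is.null(node$label)) {
      paste0(quote_label(node$label), fmt_len(node$branch %||% 0))
    } else {
      inner <- paste(vapply(node$children, walk, character(1)),
                     collapse = ",")
      paste0("(", inner, ")", fmt_len(node$branch))
    }
  }
  if (!is.null(tree$label)) {
    # degenerate single-leaf tree
    return(paste0(write_newick_leaf(tree), ";"))
  }
  paste0(walk(tree), ";")
}

write_newick_leaf <- function(node) {
  b <- node$branch %||% 0
  s <- if (b == round(b)) sprintf("%.1f", b) else sprintf("%.10g", b)
  paste0(node$label, ":", s)
}

#' Write a data frame as a '#'-headed TSV table
#'
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv_table <- function(df, path) {
  head <- paste0("#", paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  write_atomic(c(head, body), path)
}

#' Read a '#'-headed TSV table
#'
#' @param path TSV file written by [write_tsv_table()].
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#")) {
    stop("not a '#'-headed TSV table: ", path)
  }
  cols <- strsplit(substring(lines[1L], 2L), "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
    return(df)
  }
  df <- utils::read.delim(text = lines[-1L], header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE)
  df
}

#' Read a reference-to-taxon mapping table
#'
#' @param path TSV with columns `ref_id`, `taxon`.
#' @return data frame with `ref_id`, `taxon`.
#' @export
read_taxon_map <- function(path) {
  df <- read_tsv_table(path)
  if (!all(c("ref_id", "taxon") %in% names(df))) {
    stop("taxon map must have columns ref_id, taxon")
  }
  df
}
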