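AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a validated table of AHo-aligned VHH sequences
#'
#' An AHo-aligned sequence is a 149-character string over the 20 canonical
#' one-letter amino-acid codes plus the gap marker `-`. In permissive mode the
#' unknown-residue code `X` is also allowed (it never matches a hallmark).
#'
#' @param seq Character vector of 149-character gapped sequences.
#' @param id Optional identifiers (defaults to `seq1`, `seq2`, ...).
#' @param strict If `TRUE` (default), only the 20 canonical amino acids and
#'   `-` are accepted; if `FALSE`, any letter outside the canonical set is
#'   mapped to `X`.
#' @return A tibble with columns `id` and `seq`.
#' @examples
#' s <- paste(rep("A", 149), collapse = "")
#' aho_sequences(s)
#' @export
aho_sequences <- function(seq, id = NULL, strict = TRUE) {
  seq <- toupper(as.character(seq))
  if (is.null(id)) id <- paste0("seq", seq_along(seq))
  if (length(id) != length(seq)) {
    rlang::abort("`id` and `seq` must have the same length")
  }
  bad_len <- nchar(seq) != AHO_LENGTH
  if (any(bad_len)) {
    rlang::abort(sprintf(
      "AHo-aligned sequences must have exactly %d characters; offending record(s): %s",
      AHO_LENGTH, paste(id[bad_len], collapse = ", ")
    ))
  }
  alphabet <- c(AA1, "-")
  if (!strict) {
    chars <- strsplit(seq, "")
    seq <- vapply(chars, function(ch) {
      ch[!ch %in% alphabet] <- "X"
      paste(ch, collapse = "")
    }, character(1))
  } else {
    ok <- !grepl(paste0("[^", paste(AA1, collapse = ""), "-]"), seq)
    if (!all(ok)) {
      rlang::abort(sprintf(
        "illegal character(s) in strict mode in record(s): %s",
        paste(id[!ok], collapse = ", ")
      ))
    }
  }
  tibble::tibble(id = as.character(id), seq = seq)
}

#' Read AHo-aligned sequences from FASTA
#'
#' Each FASTA record must already be a 149-character gapped string (the
#' output of an AHo numbering tool). Raw, unaligned sequences are out of
#' scope: numbering is delegated to an external aligner.
#'
#' @param source Path to a FASTA file, or a character vector of FASTA text
#'   lines.
#' @inheritParams aho_sequences
#' @return A tibble with columns `id` and `seq`, in file order.
#' @export
read_aho_fasta <- function(source, strict = TRUE) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(id = character(), seq = character()))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) rlang::abort("FASTA input must start with a '>' header")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1), collapse = "")
  aho_sequences(unname(seqs), id = ids, strict = strict)
}

# 149 x n matrix of single characters, columns named by id
aho_char_matrix <- function(seqs) {
  m <- vapply(strsplit(seqs$seq, ""), identity, character(AHO_LENGTH))
  dim(m) <- c(AHO_LENGTH, nrow(seqs))
  colnames(m) <- seqs$id
  m
}

# one-letter residue at given positions of one aligned string
aho_slot <- function(seq, positions) {
  substring(seq, positions, positions)
}

#' Cysteine profile of AHo-aligned sequences
#'
#' Summarizes the cysteine content that matters for non-canonical disulphide
#' bonds (NCDBs): the conserved canonical pair sits at AHo 23 and 106; NCDBs
#' typically tether an HCDR3 cysteine (AHo 108-138) to an "anchor" cysteine
#' at AHo 40 or 57.
#'
#' @param seqs A tibble with columns `id`, `seq` (see [aho_sequences()]).
#' @return A tibble with one row per sequence: `id`, `n_cys`, `positions`
#'   (list column of sorted AHo positions), `has_canonical_pair`,
#'   `anchor_cys` and `hcdr3_cys` (list columns).
#' @export
cysteine_profile <- function(seqs) {
  pos_list <- lapply(strsplit(seqs$seq, ""), function(ch) which(ch == "C"))
  hc <- aho_positions_of("HCDR3")
  tibble::tibble(
    id = seqs$id,
    n_cys = lengths(pos_list),
    positions = pos_list,
    has_canonical_pair = vapply(pos_list, function(p) all(c(23L, 106L) %in% p), logical(1)),
    anchor_cys = lapply(pos_list, function(p) p[p %in% c(40L, 57L)]),
    hcdr3_cys = lapply(pos_list, function(p) p[p %in% hc])
  )
}

#' Flag sequences eligible for a non-canonical disulphide bond
#'
#' A sequence is an NCDB candidate when all three hold: (i) 4-5 cysteines
#' total across the domain, (ii) a cysteine at AHo 40 and/or 57, and (iii) at
#' least one cysteine inside HCDR3.
#'
#' @inheritParams cysteine_profile
#' @return The input tibble with an added logical column `ncdb_candidate`.
#' @export
ncdb_candidates <- function(seqs) {
  prof <- cysteine_profile(seqs)
  seqs$ncdb_candidate <- prof$n_cys >= 4L & prof$n_cys <= 5L &
    lengths(prof$anchor_cys) > 0L & lengths(prof$hcdr3_cys) > 0L
  seqs
}

#' Deduplicate sequences by concatenated CDR strings
#'
#' Sequences sharing identical HCDR1+HCDR2+HCDR3 strings (concatenated) are
#' collapsed to one representative. By default the first record in input
#' order survives; supply `quality` (higher is better) to pick the best
#' representative per group instead, e.g. to prefer complete, high-resolution
#' structures.
#'
#' @inheritParams cysteine_profile
#' @param quality Optional numeric vector, one value per sequence; within a
#'   duplicate group the record with the highest quality wins (ties: first in
#'   input order).
#' @return A tibble of surviving records, in input order.
#' @export
dedup_by_cdrs <- function(seqs, quality = NULL) {
  if (nrow(seqs) == 0L) return(seqs)
  key <- vapply(seqs$seq, function(s) {
    paste0(
      substr(s, 27L, 42L), substr(s, 57L, 69L), substr(s, 108L, 138L)
    )
  }, character(1), USE.NAMES = FALSE)
  if (is.null(quality)) quality <- rep(0, nrow(seqs))
  ord <- seq_len(nrow(seqs))
  keep <- tapply(ord, key, function(i) i[which.max(quality[i])])
  seqs[sort(unname(unlist(keep))), , drop = FALSE]
}
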