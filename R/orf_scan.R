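GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

translate_frame <- function(seq, offset) {
  # offset 0,1,2; returns character vector of 1-letter codes, stops as "*",
  # codons containing N as "X" (never treated as stop)
  s <- substr(seq, offset + 1, nchar(seq))
  ncod <- nchar(s) %/% 3
  if (ncod == 0L) return(character(0))
  codons <- substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N
  aa
}

longest_run <- function(aa) {
  # longest stretch of non-stop codons; ties -> 5'-most
  if (length(aa) == 0L)
    return(list(start = NA_integer_, len = 0L, peptide = ""))
  ok <- aa != "*"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (length(cand) == 0L)
    return(list(start = NA_integer_, len = 0L, peptide = ""))
  best <- cand[which.max(r$lengths[cand])]  # which.max -> first max, 5'-most
  list(start = starts[best], len = r$lengths[best],
       peptide = paste(aa[starts[best]:ends[best]], collapse = ""))
}

#' Longest stop-free peptide stretch in all six reading frames
#'
#' Translates a nucleotide sequence in frames +1/+2/+3 and the reverse
#' complement frames -1/-2/-3 with the standard genetic code and reports,
#' per frame, the longest uninterrupted run of non-stop codons (no start
#' codon required by default: a run is stop-to-stop, not ATG-initiated).
#' Codons containing N translate as X and never terminate a run. The
#' nucleotide span is 1-based and inclusive on the input strand.
#'
#' @param seq nucleotide string over A/C/G/T/N (case-insensitive),
#'   length >= 3.
#' @param require_atg restrict runs to those beginning with a Met codon.
#' @return list with `frames`, a data.frame (frame, length, start, end,
#'   peptide) for the six frames, and `best`, the row with the overall
#'   longest peptide (ties: frame order +1,+2,+3,-1,-2,-3).
#' @export
six_frame_longest <- function(seq, require_atg = FALSE) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) < 3) stop("sequence shorter than one codon")
  if (grepl("[^ACGTN]", seq)) stop("illegal characters in sequence")
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rows <- lapply(c(1, 2, 3, -1, -2, -3), function(fr) {
    s <- if (fr > 0) seq else rc
    off <- abs(fr) - 1L
    aa <- translate_frame(s, off)
    if (require_atg) {
      # truncate each run at its first Met
      runs <- longest_met_run(aa)
      res <- runs
    } else {
      res <- longest_run(aa)
    }
    if (res$len == 0L) {
      start_nt <- NA_integer_; end_nt <- NA_integer_
    } else {
      # codon positions on the translated strand
      s1 <- off + 3L * (res$start - 1L) + 1L
      s2 <- s1 + 3L * res$len - 1L
      if (fr > 0) { start_nt <- s1; end_nt <- s2 }
      else { start_nt <- L - s2 + 1L; end_nt <- L - s1 + 1L }
    }
    data.frame(frame = fr, length = res$len, start = start_nt, end = end_nt,
               peptide = res$peptide, stringsAsFactors = FALSE)
  })
  frames <- do.call(rbind, rows)
  best <- frames[which.max(frames$length), , drop = FALSE]
  list(frames = frames, best = best)
}

longest_met_run <- function(aa) {
  # longest run of non-stop codons beginning at a Met
  if (length(aa) == 0L)
    return(list(start = NA_integer_, len = 0L, peptide = ""))
  ok <- aa != "*"
  best <- list(start = NA_integer_, len = 0L, peptide = "")
  i <- 1L
  n <- length(aa)
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    j <- i
    while (j <= n && ok[j]) j <- j + 1L  # run = [i, j-1]
    mets <- which(aa[i:(j - 1L)] == "M")
    if (length(mets)) {
      st <- i + mets[1L] - 1L
      len <- j - st
      if (len > best$len)
        best <- list(start = st, len = len,
                     peptide = paste(aa[st:(j - 1L)], collapse = ""))
    }
    i <- j
  }
  best
}

#' Scan a multi-record FASTA for longest stop-free stretches
#'
#' @param fasta path to a nucleotide FASTA file.
#' @param path optional output TSV (record, frame, start, end, length,
#'   peptide).
#' @inheritParams six_frame_longest
#' @return data.frame with one row per record per frame.
#' @export
scan_fasta_orfs <- function(fasta, path = NULL, require_atg = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no records in ", fasta)
  out <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    res <- six_frame_longest(as.character(seqs[[i]]), require_atg)
    cbind(record = names(seqs)[i], res$frames)
  }))
  if (!is.null(path))
    write.table(out[, c("record", "frame", "start", "end", "length",
                        "peptide")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
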