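#' Remove read pairs with host evidence
#'
#' A pair is discarded if either read is flagged as mapping to the host
#' genome; both flags must be clear for the pair to survive.
#'
#' @param pairs Tibble of read pairs with logical `host1`, `host2` columns
#'   (as from [simulate_read_pairs()]).
#' @return The surviving pairs, in input order.
#' @export
remove_host_pairs <- function(pairs) {
  if (!all(c("host1", "host2") %in% names(pairs))) {
    input_error("`pairs` must carry host1/host2 flags")
  }
  if (anyNA(pairs$host1) || anyNA(pairs$host2)) {
    input_error("host flags must not be missing")
  }
  dplyr::filter(pairs, !.data$host1 & !.data$host2)
}

#' Quality- and adapter-trim a single read
#'
#' Removes an exact adapter suffix/prefix match, then trims bases from both
#' ends while the terminal base quality is below `phred_floor`. Internal
#' low-quality bases are retained (end-trimming, not masking); after
#' end-trimming, no retained terminal base is below the floor.
#'
#' @param seq Nucleotide string.
#' @param quals Phred+33 quality string of the same length.
#' @param phred_floor Minimum terminal base quality kept (default 30).
#' @param adapters Character vector of adapter sequences removed by exact
#'   suffix (and prefix) match before quality trimming.
#' @return List with `seq` and `quals` of the trimmed read.
#' @export
#' @examples
#' trim_read("ACGTACGT", "IIIIII##")$seq # low-quality tail removed
trim_read <- function(seq, quals, phred_floor = 30, adapters = "AGATCGGAAGAGC") {
  if (length(seq) != 1 || length(quals) != 1) input_error("trim_read is scalar; see trim_pairs()")
  if (nchar(seq) != nchar(quals)) input_error("sequence and quality lengths differ")
  s <- strsplit(seq, "")[[1]]
  q <- utf8ToInt(quals) - 33L
  for (ad in adapters) {
    k <- nchar(ad)
    n <- length(s)
    if (k > 0 && n >= k && paste(s[(n - k + 1):n], collapse = "") == ad) {
      s <- s[seq_len(n - k)]
      q <- q[seq_len(n - k)]
    }
    n <- length(s)
    if (k > 0 && n >= k && paste(s[seq_len(k)], collapse = "") == ad) {
      s <- s[-seq_len(k)]
      q <- q[-seq_len(k)]
    }
  }
  lo <- 1L
  hi <- length(q)
  while (hi >= lo && q[hi] < phred_floor) hi <- hi - 1L
  while (lo <= hi && q[lo] < phred_floor) lo <- lo + 1L
  if (hi < lo) return(list(seq = "", quals = ""))
  list(seq = paste(s[lo:hi], collapse = ""),
       quals = intToUtf8(q[lo:hi] + 33L))
}

#' Trim both mates of every pair
#'
#' @param pairs Read-pair tibble with `read1_seq`/`read1_qual`/`read2_seq`/
#'   `read2_qual` columns.
#' @inheritParams trim_read
#' @return The pairs with trimmed sequences and qualities.
#' @export
trim_pairs <- function(pairs, phred_floor = 30, adapters = "AGATCGGAAGAGC") {
  tr <- function(seqs, quals) {
    out <- purrr::map2(seqs, quals, trim_read,
                       phred_floor = phred_floor, adapters = adapters)
    list(seq = vapply(out, `[[`, "", "seq"), quals = vapply(out, `[[`, "", "quals"))
  }
  t1 <- tr(pairs$read1_seq, pairs$read1_qual)
  t2 <- tr(pairs$read2_seq, pairs$read2_qual)
  dplyr::mutate(pairs,
                read1_seq = t1$seq, read1_qual = t1$quals,
                read2_seq = t2$seq, read2_qual = t2$quals)
}

#' Length filter for high-quality non-host (HQNH) pairs
#'
#' After host removal and trimming, a pair is retained only if both mates
#' are at least `min_len` bases long.
#'
#' @param pairs Trimmed read-pair tibble.
#' @param min_len Minimum post-trimming mate length (default 100 bp).
#' @return The HQNH pairs, in input order.
#' @export
hqnh_filter <- function(pairs, min_len = 100) {
  dplyr::filter(pairs, nchar(.data$read1_seq) >= min_len &
                  nchar(.data$read2_seq) >= min_len)
}

#' Full HQNH read-pair pipeline
#'
#' Host removal, adapter/quality trimming and the both-mates >= 100 bp
#' length filter, with a per-stage accounting summary.
#'
#' @inheritParams trim_pairs
#' @inheritParams hqnh_filter
#' @return List with `pairs` (the HQNH pairs) and `summary` (a one-row
#'   tibble: `pairs_in`, `host_removed`, `after_trim`, `hqnh_out`).
#' @export
hqnh_pipeline <- function(pairs, phred_floor = 30, min_len = 100,
                          adapters = "AGATCGGAAGAGC") {
  n_in <- nrow(pairs)
  nh <- remove_host_pairs(pairs)
  tr <- trim_pairs(nh, phred_floor = phred_floor, adapters = adapters)
  out <- hqnh_filter(tr, min_len = min_len)
  list(pairs = out,
       summary = tibble(pairs_in = n_in,
                        host_removed = n_in - nrow(nh),
                        after_trim = nrow(tr),
                        hqnh_out = nrow(out)))
}

#' Write paired reads as FASTQ
#'
#' @param pairs Read-pair tibble.
#' @param r1_path,r2_path Output FASTQ paths (uncompressed, Phred+33).
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  w <- function(ids, seqs, quals, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(pairs) > 0) {
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
    }
  }
  w(pairs$read_id, pairs$read1_seq, pairs$read1_qual, r1_path)
  w(pairs$read_id, pairs$read2_seq, pairs$read2_qual, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' Uses Biostrings when available; host flags are initialized to FALSE
#' (the flags are an upstream aligner contract, not stored in FASTQ).
#'
#' @param r1_path,r2_path FASTQ paths.
#' @return Read-pair tibble as produced by [simulate_read_pairs()].
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  rd <- if (requireNamespace("Biostrings", quietly = TRUE)) {
    function(path) {
      x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
      list(id = names(x), seq = as.character(x),
           qual = as.character(Biostrings::quality(x)))
    }
  } else {
    function(path) {
      ln <- readLines(path)
      idx <- seq(1, length(ln), by = 4)
      list(id = sub("^@", "", ln[idx]), seq = ln[idx + 1], qual = ln[idx + 3])
    }
  }
  a <- rd(r1_path)
  b <- rd(r2_path)
  if (length(a$id) != length(b$id)) input_error("mate files have different pair counts")
  tibble(read_id = sub("\\s.*$", "", a$id),
         read1_seq = unname(a$seq), read1_qual = unname(a$qual),
         read2_seq = unname(b$seq), read2_qual = unname(b$qual),
         host1 = FALSE, host2 = FALSE)
}
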