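# Read-pair quality filtering and gene-catalog mapping acceptance rules.
#
# A read pair is "HQNH" (high-quality non-host) when both mates survive
# quality trimming and neither maps to the host genome. A surviving pair is
# "mapped" when its alignment to the gene catalog passes the MAPQ / length /
# identity / overhang / uniqueness rules below.

#' Quality-trim a single read
#'
#' Emulates leading/trailing base removal followed by sliding-window
#' truncation: first, leading and trailing bases with a Phred score below
#' `q_threshold` are removed; then the remaining read is scanned 5' to 3'
#' and truncated immediately before the first window of `window` bases whose
#' mean Phred score falls below `q_threshold`. Reads shorter than `min_len`
#' after trimming are flagged for discard. Adapter clipping is not performed.
#'
#' @param quality Integer vector of per-base Phred scores, or a single
#'   Phred+33 encoded quality string.
#' @param window Sliding window width in bases (default 4).
#' @param q_threshold Phred threshold (default 20) used both for the
#'   leading/trailing step and the window mean.
#' @param min_len Minimum post-trim length in bases (default 100); shorter
#'   reads are discarded.
#' @return A list with `quality` (the trimmed Phred vector), `length`,
#'   and `keep` (`FALSE` when the read is discarded).
#' @examples
#' trim_read(rep(40L, 150))$keep
#' trim_read(c(rep(40L, 95), rep(2L, 15)))$keep   # trimmed below 100 bases
#' @export
trim_read <- function(quality, window = 4, q_threshold = 20, min_len = 100) {
  if (window < 1) stop("`window` must be >= 1")
  if (min_len < 1) stop("`min_len` must be >= 1")
  q <- decode_phred(quality)
  strip_ends <- function(q) {
    keep_idx <- which(q >= q_threshold)
    if (length(keep_idx) == 0L) return(integer(0))
    q[keep_idx[1L]:keep_idx[length(keep_idx)]]
  }
  q <- strip_ends(q)
  # sliding window, full windows only, cut before the first failing window
  n <- length(q)
  if (n >= window) {
    cs <- cumsum(c(0, q))
    means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
    fail <- which(means < q_threshold)
    if (length(fail) > 0L) q <- q[seq_len(fail[1L] - 1L)]
  }
  # the window cut can expose new trailing low-quality bases; stripping them
  # again reaches the fixpoint (the surviving prefix passes all windows),
  # making the whole operation idempotent
  q <- strip_ends(q)
  list(quality = q, length = length(q), keep = length(q) >= min_len)
}

decode_phred <- function(quality) {
  if (is.character(quality)) {
    stopifnot(length(quality) == 1L)
    q <- utf8ToInt(quality) - 33L
    if (any(q < 0L | q > 93L)) stop("invalid Phred+33 quality character")
    return(q)
  }
  q <- as.integer(quality)
  if (anyNA(q) || any(q < 0L)) stop("Phred scores must be non-negative integers")
  q
}

#' Retain high-quality non-host (HQNH) read pairs
#'
#' A pair is retained iff both mates survived trimming and the pair is not
#' flagged as host-derived. Vectorized over pairs.
#'
#' @param read1_kept,read2_kept Logical: did each mate survive [trim_read()]?
#' @param is_host Logical: does the pair map to the host genome?
#' @return Logical vector, `TRUE` for HQNH pairs.
#' @export
keep_pair_hqnh <- function(read1_kept, read2_kept, is_host) {
  stopifnot(is.logical(read1_kept), is.logical(read2_kept), is.logical(is_host))
  read1_kept & read2_kept & !is_host
}

#' Mapping acceptance rule for read-pair alignments
#'
#' A read pair counts as mapped to a catalog gene when both mates have
#' MAPQ at or above `mapq_min`, the alignment is at least `min_alen` bases
#' (per mate: the shorter mate's aligned length is checked), identity is at
#' least `min_identity` percent, the pair hits a single candidate gene, and
#' no more than `max_overhang` bases at either read end fail to align.
#' All thresholds are inclusive at the stated boundary; the overhang rule
#' rejects strictly more than `max_overhang` bases.
#'
#' @param records Data frame of alignment records with columns
#'   `mapq_mate1`, `mapq_mate2`, `aligned_len_bp`, `identity_pct`,
#'   `overhang5`, `overhang3`, `n_candidate_genes`.
#' @param mapq_min Minimum MAPQ for both mates (default 20).
#' @param min_alen Minimum aligned length in bp (default 100).
#' @param min_identity Minimum percent identity (default 95).
#' @param max_overhang Maximum tolerated unaligned bases at either read end
#'   (default 10).
#' @return Logical vector, one element per record.
#' @export
accept_mapping <- function(records, mapq_min = 20, min_alen = 100,
                           min_identity = 95, max_overhang = 10) {
  need <- c("mapq_mate1", "mapq_mate2", "aligned_len_bp", "identity_pct",
            "overhang5", "overhang3", "n_candidate_genes")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  pmin(records$mapq_mate1, records$mapq_mate2) >= mapq_min &
    records$aligned_len_bp >= min_alen &
    records$identity_pct >= min_identity &
    records$n_candidate_genes == 1L &
    pmax(records$overhang5, records$overhang3) <= max_overhang
}

#' Remove duplicate read pairs
#'
#' Keeps the first record (in input order) for every duplicate key, emulating
#' coordinate-based PCR/optical duplicate removal. Output order is stable.
#'
#' @param records Data frame with a `dup_key` column (coordinate tuple).
#' @param key Column name holding the duplicate key (default `"dup_key"`).
#' @return The deduplicated data frame.
#' @export
dedup <- function(records, key = "dup_key") {
  if (!key %in% names(records)) stop("records lack a `", key, "` column")
  records[!duplicated(records[[key]]), , drop = FALSE]
}

#' Tally accepted read pairs per gene
#'
#' @param records Data frame of accepted, deduplicated alignment records
#'   with a `gene_id` column.
#' @return Named integer vector of read-pair counts per gene; the sum equals
#'   the number of input records.
#' @export
tally_gene_counts <- function(records) {
  if (nrow(records) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(records$gene_id)
  setNames(as.integer(tab), names(tab))
}

#' Per-sample read accounting
#'
#' Partitions a sample's read pairs into the four classes reported by the
#' pipeline: low quality (failed trimming), host, unmapped to the catalog,
#' and mapped. The four fractions sum to one.
#'
#' @param records Data frame with logical columns `read1_kept`, `read2_kept`,
#'   `is_host`, and a `gene_id` column that is `NA` for pairs not mapping to
#'   the catalog. Host status takes precedence after quality; a pair failing
#'   trimming is counted as low quality regardless of other flags.
#' @return Named numeric vector of fractions
#'   `c(low_quality, host, unmapped_to_catalog, mapped)`.
#' @export
read_accounting <- function(records) {
  n <- nrow(records)
  if (n == 0L) stop("no records to account for")
  lowq <- !(records$read1_kept & records$read2_kept)
  host <- !lowq & records$is_host
  unmapped <- !lowq & !host & is.na(records$gene_id)
  mapped <- !lowq & !host & !is.na(records$gene_id)
  c(low_quality = sum(lowq), host = sum(host),
    unmapped_to_catalog = sum(unmapped), mapped = sum(mapped)) / n
}
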