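DONOR_WINDOW <- c(upstream = 3L, site = 2L, downstream = 4L)     # 9 nt
ACCEPTOR_WINDOW <- c(upstream = 18L, site = 2L, downstream = 3L) # 23 nt
DNA_BASES <- c("A", "C", "G", "T")

window_width <- function(kind) {
  if (kind == "donor") sum(DONOR_WINDOW) else sum(ACCEPTOR_WINDOW)
}

#' Extract a splice-site sequence window
#'
#' Donor windows cover 3 exonic nt, the 2-nt donor site and 4 intronic nt
#' (9 nt total); acceptor windows cover 18 intronic nt (spanning the
#' polypyrimidine tract), the 2-nt acceptor site and 3 exonic nt (23 nt
#' total). Windows are returned in sense orientation: on "-" the mirrored
#' genomic interval is fetched and reverse-complemented.
#'
#' @param chrom,start,end Intron coordinates, 1-based inclusive.
#' @param strand `"+"` or `"-"` (an unresolved strand is an
#'   extraction-failure by contract; see [score_junction()]).
#' @param genome `DNAStringSet` genome.
#' @param kind `"donor"` or `"acceptor"`.
#' @return List with `seq` (or `NA`), `valid` (logical) and `reason`
#'   (`"ok"`, `"extraction_failed"` for out-of-bounds coordinates,
#'   `"invalid_bases"` for windows containing non-ACGT letters).
#' @export
extract_window <- function(chrom, start, end, strand, genome,
                           kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  stopifnot(strand %in% c("+", "-"))
  if (kind == "donor") {
    coords <- if (strand == "+") c(start - 3L, start + 5L)
              else c(end - 5L, end + 3L)
  } else {
    coords <- if (strand == "+") c(end - 19L, end + 3L)
              else c(start - 3L, start + 19L)
  }
  seq <- tryCatch(
    fetch_seq(genome, chrom, coords[1L], coords[2L],
              orientation = if (strand == "+") "forward"
                            else "reverse_complement"),
    error = function(e) NULL)
  if (is.null(seq)) {
    return(list(seq = NA_character_, valid = FALSE,
                reason = "extraction_failed"))
  }
  if (!grepl(sprintf("^[ACGT]{%d}$", window_width(kind)), seq)) {
    return(list(seq = seq, valid = FALSE, reason = "invalid_bases"))
  }
  list(seq = seq, valid = TRUE, reason = "ok")
}

#' Build a position weight matrix from sequence windows
#'
#' Per-position base probabilities with a Laplace-style pseudocount:
#' `p(pos, base) = (count(pos, base) + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param windows Character vector of equal-length ACGT windows.
#' @param pseudocount Non-negative pseudocount (default 1). With 0,
#'   unobserved bases get probability 0 and scoring such a base errors.
#' @param kind `"donor"` or `"acceptor"` (annotation only).
#' @return Object of class `pwm`: list with `prob` (4 x width matrix,
#'   rows A/C/G/T), `width`, `kind`, `pseudocount`, `training_n`.
#' @export
build_pwm <- function(windows, pseudocount = 1, kind = "donor") {
  if (length(windows) == 0L) {
    stop("cannot build a PWM from an empty training set")
  }
  w <- unique(nchar(windows))
  if (length(w) != 1L) {
    stop("training windows have mixed lengths: ",
         paste(w, collapse = ", "))
  }
  stopifnot(pseudocount >= 0)
  mat <- matrix(unlist(strsplit(windows, "")), ncol = w, byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tabulate(factor(mat[, j], levels = DNA_BASES), nbins = 4L)
  }, integer(4L))
  prob <- (counts + pseudocount) / (length(windows) + 4 * pseudocount)
  dimnames(prob) <- list(DNA_BASES, NULL)
  structure(list(prob = prob, width = w, kind = kind,
                 pseudocount = pseudocount, training_n = length(windows)),
            class = "pwm")
}

#' Score a window against a PWM
#'
#' Summed log2-odds against a uniform 0.25 background:
#' `sum over positions of log2(p(pos, base) / 0.25)`, in bits. A uniform
#' PWM scores 0 for every window.
#'
#' @param pwm A `pwm` (see [build_pwm()]).
#' @param window ACGT string of length `pwm$width`.
#' @return Score in bits.
#' @export
score_window <- function(pwm, window) {
  stopifnot(nchar(window) == pwm$width)
  bases <- strsplit(window, "")[[1L]]
  if (!all(bases %in% DNA_BASES)) {
    stop("window contains non-ACGT bases: ", window)
  }
  p <- pwm$prob[cbind(match(bases, DNA_BASES), seq_len(pwm$width))]
  if (any(p == 0)) {
    stop("zero probability at a scored position; ",
         "rebuild the PWM with pseudocount > 0")
  }
  sum(log2(p / 0.25))
}

#' Score one junction with donor and acceptor PWMs
#'
#' Extracts both windows and returns donor, acceptor and total (sum)
#' scores. Any failure yields a not-classified outcome with a reason tag.
#'
#' @param chrom,start,end Intron coordinates.
#' @param strand `"+"`, `"-"` or `"unresolved"`.
#' @param donor_pwm,acceptor_pwm Trained PWMs.
#' @param genome `DNAStringSet` genome.
#' @return List with `ok`; on success `donor_score`, `acceptor_score`,
#'   `total_score`; on failure `reason` in `strand_unresolved`,
#'   `extraction_failed`, `invalid_bases`.
#' @export
score_junction <- function(chrom, start, end, strand, donor_pwm,
                           acceptor_pwm, genome) {
  if (!strand %in% c("+", "-")) {
    return(list(ok = FALSE, reason = "strand_unresolved"))
  }
  d <- extract_window(chrom, start, end, strand, genome, "donor")
  a <- extract_window(chrom, start, end, strand, genome, "acceptor")
  if (!d$valid || !a$valid) {
    reasons <- c(d$reason, a$reason)
    reason <- if ("extraction_failed" %in% reasons) "extraction_failed"
              else "invalid_bases"
    return(list(ok = FALSE, reason = reason))
  }
  ds <- score_window(donor_pwm, d$seq)
  as_ <- score_window(acceptor_pwm, a$seq)
  list(ok = TRUE, donor_score = ds, acceptor_score = as_,
       total_score = ds + as_)
}

scramble_window <- function(window) {
  paste(sample(strsplit(window, "")[[1L]]), collapse = "")
}

#' Build a scrambled-control null score distribution
#'
#' Each null draw samples one donor and one acceptor training window
#' (uniformly, with replacement), permutes the bases within each window
#' (composition-preserving scramble), scores both against the trained
#' PWMs and records the summed total. The resulting distribution is the
#' null against which candidate total scores are thresholded.
#'
#' @param donor_pwm,acceptor_pwm Trained PWMs.
#' @param donor_windows,acceptor_windows Training windows (the canonical
#'   windows the PWMs were built from).
#' @param n_scrambles Number of null draws (default 10000, minimum 100).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Object of class `null_model`: list with `null_scores`,
#'   `n_scrambles`, `seed`.
#' @export
build_null <- function(donor_pwm, acceptor_pwm, donor_windows,
                       acceptor_windows, n_scrambles = 10000L, seed = 42L) {
  if (length(donor_windows) == 0L || length(acceptor_windows) == 0L) {
    stop("cannot build a null from an empty training set")
  }
  stopifnot(n_scrambles >= 100L)
  scores <- withr::with_seed(seed, {
    di <- sample.int(length(donor_windows), n_scrambles, replace = TRUE)
    ai <- sample.int(length(acceptor_windows), n_scrambles, replace = TRUE)
    vapply(seq_len(n_scrambles), function(k) {
      score_window(donor_pwm, scramble_window(donor_windows[di[k]])) +
        score_window(acceptor_pwm, scramble_window(acceptor_windows[ai[k]]))
    }, numeric(1L))
  })
  structure(list(null_scores = scores, n_scrambles = n_scrambles,
                 seed = seed),
            class = "null_model")
}

#' Derive the classification threshold from a null distribution
#'
#' Linear-interpolation percentile (the classic order-statistic
#' interpolation, `stats::quantile` type 7) of the null total scores.
#'
#' @param null A `null_model` (see [build_null()]).
#' @param percentile Percentile in (0, 100); default 95.
#' @return Threshold in bits.
#' @export
derive_threshold <- function(null, percentile = 95) {
  stopifnot(length(null$null_scores) > 0L,
            percentile > 0, percentile < 100)
  unname(stats::quantile(null$null_scores, percentile / 100, type = 7L))
}

#' Classify total scores against the threshold
#'
#' Scores strictly greater than the threshold are U2/U12-like; scores
#' less than or equal to it (including exact equality) are
#' non-U2/U12-like.
#'
#' @param total_score Numeric vector of total scores.
#' @param threshold Threshold in bits.
#' @return Character vector of `"u2u12_like"` / `"non_u2u12_like"`.
#' @export
classify <- function(total_score, threshold) {
  ifelse(total_score > threshold, "u2u12_like", "non_u2u12_like")
}

#' Train PWMs on canonical junctions and classify the non-canonical ones
#'
#' The full classification stage: extracts donor/acceptor windows for all
#' canonical junctions with resolved strand, trains both PWMs on the
#' valid windows, builds the scrambled null and its threshold, scores
#' every non-canonical junction and labels it `u2u12_like`,
#' `non_u2u12_like` or `not_classified` (with a reason). Canonical
#' junctions get `not_applicable`; excluded junctions `not_classified`.
#'
#' @param catalog Junction catalog (see [build_catalog()]).
#' @param genome `DNAStringSet` genome.
#' @param pseudocount PWM pseudocount (default 1).
#' @param n_scrambles Null draws (default 10000).
#' @param percentile Null percentile for the threshold (default 95).
#' @param seed Seed for the scrambled null (default 42).
#' @return List with `catalog` (input plus `classification`,
#'   `not_classified_reason`, `donor_score`, `acceptor_score`,
#'   `total_score`), `donor_pwm`, `acceptor_pwm`, `null`, `threshold`,
#'   `percentile`.
#' @export
classify_junctions <- function(catalog, genome, pseudocount = 1,
                               n_scrambles = 10000L, percentile = 95,
                               seed = 42L) {
  canon <- catalog[catalog$category == "canonical", , drop = FALSE]
  if (nrow(canon) == 0L) {
    stop("no canonical junctions available to train PWMs")
  }
  dw <- character(0)
  aw <- character(0)
  for (i in seq_len(nrow(canon))) {
    d <- extract_window(canon$chrom[i], canon$start[i], canon$end[i],
                        canon$strand[i], genome, "donor")
    a <- extract_window(canon$chrom[i], canon$start[i], canon$end[i],
                        canon$strand[i], genome, "acceptor")
    if (d$valid && a$valid) {
      dw <- c(dw, d$seq)
      aw <- c(aw, a$seq)
    }
  }
  if (length(dw) == 0L) {
    stop("no canonical junction yielded valid training windows")
  }
  donor_pwm <- build_pwm(dw, pseudocount, "donor")
  acceptor_pwm <- build_pwm(aw, pseudocount, "acceptor")
  null <- build_null(donor_pwm, acceptor_pwm, dw, aw, n_scrambles, seed)
  threshold <- derive_threshold(null, percentile)

  n <- nrow(catalog)
  catalog$classification <- rep("not_applicable", n)
  catalog$not_classified_reason <- rep(NA_character_, n)
  catalog$donor_score <- rep(NA_real_, n)
  catalog$acceptor_score <- rep(NA_real_, n)
  catalog$total_score <- rep(NA_real_, n)
  for (i in which(catalog$category != "canonical")) {
    if (catalog$category[i] == "excluded") {
      catalog$classification[i] <- "not_classified"
      catalog$not_classified_reason[i] <-
        if (catalog$strand[i] %in% c("+", "-")) "invalid_bases"
        else "strand_unresolved"
      next
    }
    sc <- score_junction(catalog$chrom[i], catalog$start[i], catalog$end[i],
                         catalog$strand[i], donor_pwm, acceptor_pwm, genome)
    if (!sc$ok) {
      catalog$classification[i] <- "not_classified"
      catalog$not_classified_reason[i] <- sc$reason
    } else {
      catalog$donor_score[i] <- sc$donor_score
      catalog$acceptor_score[i] <- sc$acceptor_score
      catalog$total_score[i] <- sc$total_score
      catalog$classification[i] <- classify(sc$total_score, threshold)
    }
  }
  list(catalog = catalog, donor_pwm = donor_pwm,
       acceptor_pwm = acceptor_pwm, null = null, threshold = threshold,
       percentile = percentile)
}

#' Export a PWM as a long-format table
#'
#' @param pwm A `pwm`.
#' @return Data.frame with `position`, `base`, `probability`.
#' @export
pwm_table <- function(pwm) {
  data.frame(position = rep(seq_len(pwm$width), each = 4L),
             base = rep(DNA_BASES, pwm$width),
             probability = as.vector(pwm$prob),
             stringsAsFactors = FALSE)
}
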