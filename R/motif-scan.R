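# RBP motif machinery: ATtRACT-style PWM loading and cleaning, exact
# p-value score thresholds via dynamic programming over discretized
# log-odds scores, sliding-window scanning in both orientations,
# dinucleotide-preserving shuffles, and sequence-level Fisher enrichment.

NUC <- c("A", "C", "G", "T")

#' Zero-order background model from a sequence set
#'
#' Single-nucleotide frequencies across the given sequences (e.g. the
#' circRNA sequences of the cohort), with a +1 pseudocount per nucleotide so
#' every frequency is strictly positive.
#'
#' @param sequences character vector (or `DNAStringSet`) of ACGT sequences.
#' @return named numeric vector of frequencies summing to 1.
#' @export
background_model <- function(sequences) {
  sequences <- as.character(sequences)
  counts <- stats::setNames(numeric(4), NUC)
  tab <- table(strsplit(paste(sequences, collapse = ""), "")[[1]])
  hit <- intersect(names(tab), NUC)
  counts[hit] <- as.numeric(tab[hit])
  (counts + 1) / sum(counts + 1)
}

new_motif <- function(motif_id, rbp_names, matrix, consensus) {
  structure(list(motif_id = motif_id, rbp_names = rbp_names,
                 matrix = matrix, consensus = consensus,
                 length = nrow(matrix), orientation = "given"),
            class = "motif_pwm")
}

#' Reverse complement of a PWM
#'
#' @param motif a `motif_pwm`.
#' @return the motif with rows reversed and A/T, C/G columns swapped;
#'   `orientation` becomes `reverse_complement`.
#' @export
pwm_revcomp <- function(motif) {
  m <- motif$matrix[rev(seq_len(nrow(motif$matrix))), c("T", "G", "C", "A"),
                    drop = FALSE]
  colnames(m) <- NUC
  out <- motif
  out$matrix <- m
  out$consensus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif$consensus)))
  out$orientation <- if (motif$orientation == "given") "reverse_complement"
                     else "given"
  out
}

#' Load and clean an ATtRACT-style motif collection
#'
#' The database table must carry columns `Matrix_id`, `Gene_name`, and
#' `Motif` (consensus); the PWM file holds blocks of the form
#' `>Matrix_id<TAB>length` followed by one row of four probabilities
#' (A C G T order) per position. Cleaning drops entries whose PWM length
#' differs from their consensus length and motifs shorter than `min_len`;
#' entries with identical matrices are merged into one (RBP names pooled and
#' sorted). Rows not summing to 1 are renormalized with a warning;
#' non-finite entries reject the motif.
#'
#' @param db_path ATtRACT-style TSV.
#' @param pwm_path PWM text file.
#' @param min_len minimum motif length kept.
#' @return list of `motif_pwm` objects (class `motif_db`).
#' @export
load_motif_db <- function(db_path, pwm_path, min_len = 6L) {
  db <- utils::read.delim(db_path, stringsAsFactors = FALSE)
  need <- c("Matrix_id", "Gene_name", "Motif")
  if (!all(need %in% colnames(db)))
    stop("load_motif_db: database table needs columns ",
         paste(need, collapse = ", "))
  lines <- readLines(pwm_path)
  hdr <- grep("^>", lines)
  pwms <- list()
  for (k in seq_along(hdr)) {
    meta <- strsplit(sub("^>", "", lines[hdr[k]]), "\t")[[1]]
    id <- meta[1]
    to <- if (k < length(hdr)) hdr[k + 1] - 1L else length(lines)
    block <- lines[(hdr[k] + 1L):to]
    block <- block[nzchar(trimws(block))]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    colnames(m) <- NUC
    pwms[[id]] <- m
  }
  motifs <- list()
  for (i in seq_len(nrow(db))) {
    id <- db$Matrix_id[i]
    m <- pwms[[id]]
    if (is.null(m)) next
    consensus <- toupper(db$Motif[i])
    if (nrow(m) != nchar(consensus)) next      # spurious entry
    if (nrow(m) < min_len) next                # shorter than 6-mers
    if (any(!is.finite(m))) {
      warning("load_motif_db: non-finite PWM entries, rejecting ", id)
      next
    }
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-4)) {
      warning("load_motif_db: renormalizing PWM rows of ", id)
      m <- m / rs
    }
    key <- paste(sprintf("%.6f", t(m)), collapse = ",")
    if (!is.null(motifs[[key]])) {
      motifs[[key]]$rbp_names <- sort(unique(c(motifs[[key]]$rbp_names,
                                               db$Gene_name[i])))
      motifs[[key]]$motif_id <- paste(sort(unique(c(
        strsplit(motifs[[key]]$motif_id, "/")[[1]], id))), collapse = "/")
    } else {
      motifs[[key]] <- new_motif(id, db$Gene_name[i], m, consensus)
    }
  }
  out <- unname(motifs)
  class(out) <- "motif_db"
  out
}

# discretized per-position log-odds scores (integer units of `granularity`)
pwm_score_matrix <- function(motif, background, prob_floor = 1e-3,
                             granularity = 1e-3) {
  s <- log2(pmax(motif$matrix, prob_floor) /
              rep(background[NUC], each = nrow(motif$matrix)))
  round(s / granularity)
}

#' Exact score cutoff of a PWM at a p-value under a background
#'
#' Per-position log2 odds scores (probabilities floored at `prob_floor`) are
#' discretized to `granularity`; the exact null score distribution over all
#' words is computed by dynamic programming over positions, and the cutoff
#' is the smallest attainable score s with P(score >= s) < `pvalue` under
#' the zero-order background. When no attainable score qualifies the cutoff
#' is `+Inf` (the motif can never match).
#'
#' @param motif a `motif_pwm`.
#' @param background named frequency vector ([background_model()]).
#' @param pvalue match p-value cutoff.
#' @param prob_floor floor applied to PWM probabilities before the log.
#' @param granularity score discretization step.
#' @return list of class `pwm_threshold`: `cutoff` (real score, possibly
#'   `Inf`), `cutoff_int`, `p_at_cutoff`, `scores_int` (discretized score
#'   matrix), `null` (data.frame score_int, prob, tail), `granularity`.
#' @export
score_threshold <- function(motif, background, pvalue = 1e-4,
                            prob_floor = 1e-3, granularity = 1e-3) {
  stopifnot(all(background > 0))
  sd_mat <- pwm_score_matrix(motif, background, prob_floor, granularity)
  b <- background[NUC]
  # distribution over integer scores, kept as a dense vector with offset
  cur_lo <- 0L
  acc <- c(1)
  for (j in seq_len(nrow(sd_mat))) {
    sj <- sd_mat[j, ]
    new_lo <- cur_lo + min(sj)
    new_hi <- cur_lo + length(acc) - 1L + max(sj)
    new <- numeric(new_hi - new_lo + 1L)
    for (n in 1:4) {
      shift <- cur_lo + sj[n] - new_lo
      idx <- seq_along(acc) + shift
      new[idx] <- new[idx] + acc * b[n]
    }
    acc <- new
    cur_lo <- new_lo
  }
  support <- which(acc > 0)
  scores_int <- cur_lo + support - 1L
  probs <- acc[support]
  tails <- rev(cumsum(rev(probs)))
  qual <- which(tails < pvalue)
  if (length(qual) == 0) {
    cutoff_int <- Inf; cutoff <- Inf; p_at <- NA_real_
  } else {
    k <- qual[1]
    cutoff_int <- scores_int[k]
    cutoff <- cutoff_int * granularity
    p_at <- tails[k]
  }
  structure(list(cutoff = cutoff, cutoff_int = cutoff_int,
                 p_at_cutoff = p_at, scores_int = sd_mat,
                 null = data.frame(score_int = scores_int, prob = probs,
                                   tail = tails),
                 granularity = granularity),
            class = "pwm_threshold")
}

# integer window scores of a coded sequence against a discretized score
# matrix; windows containing non-ACGT positions are flagged invalid
score_windows <- function(code, sd_mat) {
  L <- nrow(sd_mat)
  n <- length(code) - L + 1L
  if (n <= 0) return(list(score = integer(0), valid = logical(0)))
  total <- integer(n)
  valid <- rep(TRUE, n)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n - 1L)]
    bad <- is.na(cj)
    valid <- valid & !bad
    cj[bad] <- 1L
    total <- total + sd_mat[j, cj]
  }
  list(score = total, valid = valid)
}

#' Scan sequences for significant PWM matches
#'
#' Every sliding window (both the given and reverse-complement orientation
#' of each motif) with a discretized score at or above the motif's exact
#' p-value cutoff counts one hit; overlapping hits count individually.
#' Windows containing non-ACGT symbols are skipped and tallied.
#'
#' @param sequences named character vector (or `DNAStringSet`).
#' @param motifs a `motif_db` (or list of `motif_pwm`).
#' @param background named frequency vector.
#' @param pvalue match p-value cutoff.
#' @param prob_floor,granularity see [score_threshold()].
#' @return list: `hits` (sequence x motif integer matrix) and
#'   `skipped_windows` (same shape).
#' @export
scan_sequences <- function(sequences, motifs, background, pvalue = 1e-4,
                           prob_floor = 1e-3, granularity = 1e-3) {
  nm <- names(sequences)
  sequences <- as.character(sequences)
  names(sequences) <- if (is.null(nm))
    sprintf("seq%04d", seq_along(sequences)) else nm
  ids <- vapply(motifs, `[[`, "", "motif_id")
  hits <- matrix(0L, length(sequences), length(motifs),
                 dimnames = list(names(sequences), ids))
  skipped <- hits
  codes <- lapply(sequences, function(s)
    match(strsplit(toupper(s), "")[[1]], NUC))
  for (k in seq_along(motifs)) {
    mt <- motifs[[k]]
    thr <- list(score_threshold(mt, background, pvalue, prob_floor,
                                granularity),
                score_threshold(pwm_revcomp(mt), background, pvalue,
                                prob_floor, granularity))
    for (i in seq_along(codes)) {
      h <- 0L; sk <- 0L
      for (t in thr) {
        if (!is.finite(t$cutoff_int)) next
        w <- score_windows(codes[[i]], t$scores_int)
        h <- h + sum(w$valid & w$score >= t$cutoff_int)
        sk <- sk + sum(!w$valid)
      }
      hits[i, k] <- h
      skipped[i, k] <- sk
    }
  }
  list(hits = hits, skipped_windows = skipped)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: the output has the identical dinucleotide
#' multiset as the input (hence identical first and last nucleotide) and is
#' drawn uniformly over the Eulerian arrangements, via rejection sampling of
#' the last-exit edges.
#'
#' @param sequence ACGT string of length >= 2.
#' @param seed optional integer seed for a private RNG stream.
#' @return shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  run <- function() {
    s <- match(strsplit(toupper(sequence), "")[[1]], NUC)
    if (anyNA(s)) stop("dinucleotide_shuffle: non-ACGT symbols")
    n <- length(s)
    if (n < 2L) stop("dinucleotide_shuffle: length >= 2 required")
    last <- s[n]
    edges <- lapply(1:4, function(v) s[which(s[-n] == v) + 1L])
    present <- which(lengths(edges) > 0)
    # choose last-exit edges forming an arborescence into the end vertex
    repeat {
      last_exit <- rep(NA_integer_, 4)
      for (v in present) if (v != last)
        last_exit[v] <- edges[[v]][sample.int(length(edges[[v]]), 1L)]
      ok <- TRUE
      for (v in present) {
        if (v == last) next
        seen <- logical(4)
        u <- v
        while (u != last) {
          if (seen[u] || is.na(last_exit[u])) { ok <- FALSE; break }
          seen[u] <- TRUE
          u <- last_exit[u]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # permute the remaining edges; append the designated last-exit edge
    ordered <- vector("list", 4)
    for (v in 1:4) {
      ev <- edges[[v]]
      if (length(ev) == 0) { ordered[[v]] <- integer(0); next }
      if (v == last || is.na(last_exit[v])) {
        ordered[[v]] <- ev[sample.int(length(ev))]
      } else {
        drop1 <- which(ev == last_exit[v])[1]
        rest <- ev[-drop1]
        ordered[[v]] <- c(rest[sample.int(length(rest))], last_exit[v])
      }
    }
    ptr <- integer(4)
    res <- integer(n)
    res[1] <- s[1]
    cur <- s[1]
    for (i in 2:n) {
      ptr[cur] <- ptr[cur] + 1L
      nxt <- ordered[[cur]][ptr[cur]]
      res[i] <- nxt
      cur <- nxt
    }
    paste(NUC[res], collapse = "")
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

#' Motif enrichment between target and control sequence sets
#'
#' Per motif, a 2x2 table of sequences bearing at least one significant hit
#' (target vs control), tested one-sided for target enrichment with
#' Fisher's exact test and Benjamini-Hochberg adjusted across motifs.
#'
#' @param targets,controls character vectors (or `DNAStringSet`) of
#'   sequences; both non-empty.
#' @param motifs a `motif_db`.
#' @param background named frequency vector.
#' @param pvalue match p-value cutoff for the scan.
#' @return data.frame: motif_id, rbp_names, target_with, target_total,
#'   control_with, control_total, odds_ratio, p.value, q.value.
#' @export
motif_enrichment <- function(targets, controls, motifs, background,
                             pvalue = 1e-4) {
  stopifnot(length(targets) > 0, length(controls) > 0)
  if (length(motifs) == 0)
    return(data.frame(motif_id = character(0)))
  th <- scan_sequences(targets, motifs, background, pvalue)$hits
  ch <- scan_sequences(controls, motifs, background, pvalue)$hits
  a <- colSums(th >= 1); b <- nrow(th) - a
  c_ <- colSums(ch >= 1); d <- nrow(ch) - c_
  p <- vapply(seq_along(a), function(k)
    stats::fisher.test(matrix(c(a[k], b[k], c_[k], d[k]), 2, byrow = TRUE),
                       alternative = "greater")$p.value, numeric(1))
  data.frame(
    motif_id = colnames(th),
    rbp_names = vapply(motifs, function(m)
      paste(m$rbp_names, collapse = ","), character(1)),
    target_with = as.integer(a), target_total = nrow(th),
    control_with = as.integer(c_), control_total = nrow(ch),
    odds_ratio = (a * d) / (b * c_),
    p.value = p, q.value = stats::p.adjust(p, "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
}
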