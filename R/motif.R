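# Ungapped motif discovery and scanning: one-occurrence-per-sequence (OOPS)
# expectation-maximization for a position weight matrix, an exact
# convolution null for window log-odds scores, best-hit scanning with
# per-sequence p- and E-values, and per-family recovery rates.

#' @keywords internal
new_pwm <- function(mat, background, loglik = NA_real_) {
  stopifnot(nrow(mat) == 20, all(abs(colSums(mat) - 1) < 1e-9))
  rownames(mat) <- AA20
  ic <- sum(colSums(mat * log2(pmax(mat, 1e-300) / background)))
  structure(list(mat = mat, background = background, width = ncol(mat),
                 information_content = ic, loglik = loglik),
            class = "mh_pwm")
}

#' @export
print.mh_pwm <- function(x, ...) {
  cons <- paste(AA20[apply(x$mat, 2, which.max)], collapse = "")
  cat(sprintf("PWM width %d, IC %.1f bits, consensus %s\n",
              x$width, x$information_content, cons))
  invisible(x)
}

#' Consensus string of a PWM
#' @param pwm an \code{mh_pwm}.
#' @return residue string of per-position argmax residues.
#' @export
pwm_consensus <- function(pwm) {
  paste(AA20[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Write / read a PWM as a plain-text matrix
#'
#' Rows are motif positions, columns the 20 residues (a minimal
#' MEME-style probability matrix).
#'
#' @param pwm an \code{mh_pwm}.
#' @param path file path.
#' @return \code{write_pwm}: \code{path} invisibly; \code{read_pwm}: an
#'   \code{mh_pwm}.
#' @export
write_pwm <- function(pwm, path) {
  m <- t(pwm$mat)
  colnames(m) <- AA20
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  new_pwm(t(m[, AA20, drop = FALSE]), RR_BACKGROUND)
}

#' @keywords internal
window_scores <- function(enc, logodds, w) {
  # log-odds score of every length-w window of an encoded sequence
  nw <- length(enc) - w + 1
  sc <- numeric(nw)
  for (k in seq_len(w)) {
    sc <- sc + logodds[cbind(enc[k:(k + nw - 1)], k)]
  }
  sc
}

#' Discover an ungapped motif by OOPS expectation-maximization
#'
#' Fits a position weight matrix under the one-occurrence-per-sequence
#' model: the E-step computes a posterior over start positions in each
#' sequence (uniform prior), the M-step re-estimates the PWM from
#' posterior-weighted counts with background pseudocounts of total weight
#' 0.1. Iteration stops when the log-likelihood improves by less than
#' \code{tol} or after \code{max_iter} iterations. Starts are initialized
#' from observed windows of the sequences: \code{n_screen} candidate
#' windows are ranked by their starting likelihood on a subsample, the
#' best \code{n_starts} are run to convergence, and each converged model
#' is register-refined by testing small site shifts (the local optima of
#' OOPS EM often sit a few columns off the best register). The highest
#' final likelihood wins.
#'
#' @param seqs list of \code{mh_sequence} records, all at least
#'   \code{width} long.
#' @param width motif width, 8 to 50 residues.
#' @param n_starts number of EM restarts (>= 1).
#' @param seed integer seed.
#' @param max_iter,tol EM stopping controls.
#' @param n_screen candidate start windows screened per discovery.
#' @param background background frequencies.
#' @return list with \code{pwm} (an \code{mh_pwm}; its \code{loglik} is the
#'   OOPS log-likelihood up to the constant background term), \code{sites}
#'   (data frame: id, start = posterior mode, posterior), and
#'   \code{loglik_trace} of the winning restart.
#' @export
discover_motif_oops <- function(seqs, width, n_starts = 5, seed = 1,
                                max_iter = 200, tol = 1e-6, n_screen = 200,
                                background = RR_BACKGROUND) {
  if (width < 8 || width > 50) stop("motif width must be in [8, 50]")
  stopifnot(n_starts >= 1, n_screen >= n_starts)
  lens <- vapply(seqs, function(s) nchar(residues_of(s)), integer(1))
  if (any(lens < width)) stop("all sequences must be at least `width` long")
  encs <- lapply(seqs, function(s) encode_residues(residues_of(s)))
  e_step <- function(mat, subset = seq_along(encs)) {
    logodds <- rbind(log(mat / background), X = 0)
    post <- vector("list", length(subset))
    ll <- 0
    for (ii in seq_along(subset)) {
      sc <- window_scores(encs[[subset[ii]]], logodds, width)
      mx <- max(sc)
      p <- exp(sc - mx)
      post[[ii]] <- p / sum(p)
      ll <- ll + mx + log(mean(p))
    }
    list(post = post, ll = ll)
  }
  m_step <- function(post) {
    counts <- matrix(0, 21, width)
    for (i in seq_along(encs)) {
      e <- encs[[i]]; pp <- post[[i]]
      nw <- length(pp)
      for (k in seq_len(width)) {
        acc <- rowsum(pp, e[k:(k + nw - 1)])
        ridx <- as.integer(rownames(acc))
        counts[ridx, k] <- counts[ridx, k] + acc[, 1]
      }
    }
    cnt20 <- counts[1:20, , drop = FALSE]
    sweep(cnt20 + 0.1 * background, 2, colSums(cnt20) + 0.1, "/")
  }
  seed_mat <- function(wmer) {
    init <- matrix(rep(background * 0.5, width), nrow = 20)
    for (k in seq_len(width)) {
      if (wmer[k] <= 20) init[wmer[k], k] <- init[wmer[k], k] + 0.5
      else init[, k] <- background   # X in the seed window
    }
    sweep(init, 2, colSums(init), "/")
  }
  pwm_from_sites <- function(starts) {
    counts <- matrix(0, 20, width)
    for (i in seq_along(encs)) {
      wm <- encs[[i]][starts[i]:(starts[i] + width - 1)]
      ok <- wm <= 20
      counts[cbind(wm[ok], which(ok))] <- counts[cbind(wm[ok], which(ok))] + 1
    }
    sweep(counts + 0.1 * background, 2, colSums(counts) + 0.1, "/")
  }
  em_run <- function(init_mat) {
    mat <- init_mat
    prev_ll <- -Inf
    trace <- numeric(0)
    post <- NULL
    for (it in seq_len(max_iter)) {
      es <- e_step(mat)
      post <- es$post
      trace <- c(trace, es$ll)
      mat_new <- m_step(post)
      if (is.finite(prev_ll) && es$ll - prev_ll < tol) {
        mat <- mat_new
        break
      }
      prev_ll <- es$ll
      mat <- mat_new
    }
    list(mat = mat, ll = trace[length(trace)], trace = trace, post = post)
  }
  refine_register <- function(run) {
    # hill-climb over small site shifts: OOPS local optima often sit a few
    # columns off the register that maximizes the likelihood
    repeat {
      improved <- FALSE
      starts <- vapply(run$post, which.max, integer(1))
      for (s in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
        sh <- pmin(pmax(starts + s, 1L), lens - width + 1L)
        cand <- em_run(pwm_from_sites(sh))
        if (cand$ll > run$ll + 1e-9) {
          run <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    run
  }
  best <- NULL
  with_seed(seed, {
    # screen candidate start windows by their one-E-step likelihood on a
    # subsample, then run the most promising ones to convergence
    sub <- if (length(encs) > 20) sample(length(encs), 20) else seq_along(encs)
    cand_i <- sample(length(encs), n_screen, replace = TRUE)
    cand_j <- vapply(cand_i, function(i) sample(lens[i] - width + 1, 1),
                     integer(1))
    screen_ll <- vapply(seq_len(n_screen), function(k) {
      wm <- encs[[cand_i[k]]][cand_j[k]:(cand_j[k] + width - 1)]
      e_step(seed_mat(wm), sub)$ll
    }, numeric(1))
    top <- order(screen_ll, decreasing = TRUE)[seq_len(n_starts)]
    for (k in top) {
      wm <- encs[[cand_i[k]]][cand_j[k]:(cand_j[k] + width - 1)]
      run <- refine_register(em_run(seed_mat(wm)))
      if (is.null(best) || run$ll > best$ll) best <- run
    }
  })
  sites <- data.frame(
    id = vapply(seqs, function(s) id_of(s), character(1)),
    start = vapply(best$post, which.max, integer(1)),
    posterior = vapply(best$post, max, numeric(1)),
    stringsAsFactors = FALSE)
  list(pwm = new_pwm(best$mat, background, loglik = best$ll),
       sites = sites, loglik_trace = best$trace)
}

#' Exact null distribution of PWM window scores
#'
#' Distribution of the summed log-odds score of a length-w background
#' window, computed by position-wise convolution over scores discretized at
#' \code{resolution} bits.
#'
#' @param pwm an \code{mh_pwm}.
#' @param resolution score bin width (bits).
#' @return an object of class \code{mh_score_dist}: \code{score} (bin
#'   centers, bits), \code{prob}, and \code{tail} with
#'   \eqn{P(S \ge score)}.
#' @export
pwm_score_distribution <- function(pwm, resolution = 0.01) {
  stopifnot(inherits(pwm, "mh_pwm"), resolution > 0)
  lo <- log2(pwm$mat / pwm$background)         # 20 x w, bits
  bins <- round(lo / resolution)
  offset_min <- 0L
  dist <- c(1)                                  # prob over bin offsets
  names(dist) <- "0"
  cur_min <- 0L
  for (k in seq_len(pwm$width)) {
    bk <- bins[, k]
    lo_k <- min(bk); hi_k <- max(bk)
    new_min <- cur_min + lo_k
    new_max <- cur_min + length(dist) - 1L + hi_k
    nd <- numeric(new_max - new_min + 1L)
    for (a in 1:20) {
      sh <- cur_min + bk[a] - new_min
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * pwm$background[a]
    }
    dist <- nd
    cur_min <- new_min
  }
  score <- (cur_min + seq_along(dist) - 1L) * resolution
  tail_p <- rev(cumsum(rev(dist)))
  structure(list(score = score, prob = dist, tail = tail_p,
                 resolution = resolution, width = pwm$width),
            class = "mh_score_dist")
}

#' @keywords internal
tail_probability <- function(dist, s) {
  # P(window score >= s) under the exact background null
  i <- findInterval(s - dist$resolution / 2, dist$score) + 1L
  if (i > length(dist$tail)) return(0)
  if (i < 1) return(1)
  dist$tail[i]
}

#' Scan sequences with a PWM
#'
#' For each sequence the best window log-odds score is converted to a
#' per-sequence p-value via the exact background null,
#' \eqn{p_{seq} = 1 - (1 - p_{window})^{L - w + 1}}, and to an E-value
#' \eqn{E = p_{seq} \times} number of scanned sequences. One best hit per
#' sequence is reported; hits with \eqn{E \le} threshold are returned.
#'
#' @param pwm an \code{mh_pwm}.
#' @param seqs list of \code{mh_sequence} records.
#' @param evalue_threshold E-value cutoff.
#' @param dist optional precomputed \code{\link{pwm_score_distribution}}.
#' @return data frame of hits: \code{id}, \code{start}, \code{score}
#'   (bits), \code{pvalue}, \code{evalue}. Sequences shorter than the PWM
#'   are skipped with a warning.
#' @export
scan_sequences <- function(pwm, seqs, evalue_threshold = 1e-4, dist = NULL) {
  stopifnot(inherits(pwm, "mh_pwm"))
  if (is.null(dist)) dist <- pwm_score_distribution(pwm)
  logodds <- rbind(log2(pwm$mat / pwm$background), X = 0)
  n_scanned <- length(seqs)
  rows <- lapply(seqs, function(s) {
    res <- residues_of(s)
    L <- nchar(res)
    if (L < pwm$width) {
      warning("sequence '", id_of(s), "' shorter than motif width; skipped")
      return(NULL)
    }
    sc <- window_scores(encode_residues(res), logodds, pwm$width)
    best <- which.max(sc)
    p_win <- tail_probability(dist, sc[best])
    p_seq <- 1 - (1 - min(p_win, 1))^(L - pwm$width + 1)
    data.frame(id = id_of(s), start = best, score = sc[best],
               pvalue = p_seq, evalue = p_seq * n_scanned,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(id = character(0), start = integer(0),
                                      score = numeric(0), pvalue = numeric(0),
                                      evalue = numeric(0)))
  out[out$evalue <= evalue_threshold, , drop = FALSE]
}

#' Motif recovery rate of a family
#'
#' @param hits hit table from \code{\link{scan_sequences}}.
#' @param family_members character vector of member ids.
#' @return percentage of members with at least one hit.
#' @examples
#' recovery_rate(data.frame(id = letters[1:21]), letters[1:26])  # 80.77
#' @export
recovery_rate <- function(hits, family_members) {
  stopifnot(length(family_members) > 0)
  100 * sum(family_members %in% hits$id) / length(family_members)
}

#' Locate motif hits on topologies
#'
#' Each hit is assigned to the membrane segment containing its midpoint
#' (\code{"TMS k"} / \code{"RL k"} numbering membrane segments from the N
#' terminus) or to \code{"loop"}.
#'
#' @param hits hit table from \code{\link{scan_sequences}}.
#' @param topos named list of \code{mh_topology} (per sequence id).
#' @param width motif width used for the scan.
#' @return table of segment labels (the per-family histogram).
#' @export
locate_motif <- function(hits, topos, width) {
  if (nrow(hits) == 0) return(table(character(0)))
  labs <- vapply(seq_len(nrow(hits)), function(i) {
    topo <- topos[[hits$id[i]]]
    if (is.null(topo)) return(NA_character_)
    mid <- hits$start[i] + floor((width - 1) / 2)
    segs <- membrane_segments(topo)
    j <- which(segs$start <= mid & segs$end >= mid)
    if (length(j) == 0) "loop" else paste(segs$kind[j], j)
  }, character(1))
  table(labs[!is.na(labs)])
}
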