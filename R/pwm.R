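#' Build PWM weights from per-column base frequencies
#'
#' Log-odds weights against a background distribution:
#' \code{w_bi = log2( ((f_bi + pseudocount * q_b) / (1 + pseudocount)) / q_b )}.
#'
#' @param freqs 4 x L numeric matrix of base frequencies, rows named A,C,G,T;
#'   columns sum to 1 within tolerance.
#' @param background Background base probabilities (named, default uniform).
#' @param pseudocount Non-negative pseudocount weight.
#' @return 4 x L numeric weight matrix, rows A,C,G,T.
#' @export
pwm_from_frequencies <- function(freqs,
                                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                 pseudocount = 0.01) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L) stop("frequency matrix must have 4 rows (A,C,G,T)")
  if (is.null(rownames(freqs))) rownames(freqs) <- c("A", "C", "G", "T")
  freqs <- freqs[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background[c("A", "C", "G", "T")]
  cs <- colSums(freqs)
  if (any(abs(cs - 1) > 1e-4)) stop("frequency columns must sum to 1")
  freqs <- sweep(freqs, 2, cs, "/")
  if (pseudocount == 0 && any(freqs == 0)) {
    stop("zero frequency with zero pseudocount gives an infinite weight")
  }
  adj <- sweep(freqs, 1, pseudocount * background, "+") / (1 + pseudocount)
  log2(sweep(adj, 1, background, "/"))
}

#' Construct a core promoter element PWM object
#'
#' @param name Identifier (e.g. "TATA").
#' @param weights 4 x L weight matrix (rows A,C,G,T), e.g. from
#'   \code{\link{pwm_from_frequencies}}.
#' @param cutoff Inclusive score threshold for calling a hit; must not exceed
#'   the maximum achievable score.
#' @param expected_position Start coordinate (relative to the TSS) of the
#'   motif's canonical location.
#' @param functional_halfwidth Half-width of the functional window (default 2,
#'   i.e. the window [expected_position - 2, expected_position + 2]).
#' @param requires Optional name of a CPE that must also be present in its own
#'   functional window for hits of this CPE to be reported (DPE requires Inr).
#' @return Object of class \code{cpe_pwm}.
#' @export
cpe_pwm <- function(name, weights, cutoff, expected_position,
                    functional_halfwidth = 2L, requires = NULL) {
  weights <- as.matrix(weights)
  maxs <- pwm_max_score(weights)
  if (cutoff > maxs + 1e-9) {
    stop("cutoff ", cutoff, " exceeds maximum achievable score ", maxs)
  }
  structure(list(name = name, weights = weights, cutoff = cutoff,
                 expected_position = as.integer(expected_position),
                 functional_halfwidth = as.integer(functional_halfwidth),
                 requires = requires),
            class = "cpe_pwm")
}

#' Maximum achievable PWM score (sum of per-column maxima)
#' @param weights 4 x L weight matrix or a \code{cpe_pwm}.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(weights) {
  if (inherits(weights, "cpe_pwm")) weights <- weights$weights
  sum(apply(weights, 2, max))
}

#' Consensus oligonucleotide of a PWM (per-column argmax; ties -> first of A,C,G,T)
#' @param pwm A \code{cpe_pwm} or weight matrix.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  w <- if (inherits(pwm, "cpe_pwm")) pwm$weights else pwm
  paste(rownames(w)[apply(w, 2, which.max)], collapse = "")
}

#' Load the CPE PWM asset file
#'
#' The package ships twelve core promoter element matrices (TATA, Inr, BREu,
#' BREd, DPE, MTE, DCE I-III, XCPE1, TCT, Pause Button) as an editable YAML
#' file: per CPE a base-frequency matrix, a cutoff expressed as a fraction of
#' the maximum achievable score, the expected start position relative to the
#' TSS, and an optional required partner CPE.
#'
#' @param path YAML file; default the shipped asset.
#' @param pseudocount Passed to \code{\link{pwm_from_frequencies}}.
#' @return Named list of \code{cpe_pwm} objects.
#' @export
load_pwms <- function(path = system.file("extdata", "pwms.yaml",
                                         package = "enhancerCGI"),
                      pseudocount = 0.01) {
  spec <- yaml::read_yaml(path)
  pwms <- lapply(spec, function(s) {
    fr <- do.call(rbind, s$frequencies)
    rownames(fr) <- c("A", "C", "G", "T")
    w <- pwm_from_frequencies(fr, pseudocount = pseudocount)
    cutoff <- s$cutoff_fraction * pwm_max_score(w)
    cpe_pwm(s$name, w, cutoff, s$expected_position,
            functional_halfwidth = if (is.null(s$functional_halfwidth)) 2L
                                   else s$functional_halfwidth,
            requires = s$requires)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  pwms
}

# Score every window start of a character-coded sequence against a PWM.
# Returns a numeric vector (NA where the window contains N or runs off the end).
pwm_score_vector <- function(codes, weights) {
  L <- length(codes)
  ell <- ncol(weights)
  n <- L - ell + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (i in seq_len(ell)) {
    sc <- sc + weights[cbind(codes[i:(i + n - 1L)], i)]
  }
  sc
}

seq_to_codes <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- match(ch, c("A", "C", "G", "T"))   # N and others -> NA -> no match
  m
}

#' Scan an anchored sequence with one PWM
#'
#' Every start position whose window score is >= the cutoff yields a hit.
#' Windows containing N are non-matches. Coordinates are relative to the
#' anchor (TSS).
#'
#' @param anchored An \code{anchored_seq}, typically covering [-500, +200].
#' @param pwm A \code{cpe_pwm}.
#' @return data.frame with columns cpe_name, start (relative), score.
#' @export
scan_pwm <- function(anchored, pwm) {
  codes <- seq_to_codes(anchored$seq)
  sc <- pwm_score_vector(codes, pwm$weights)
  hit <- which(!is.na(sc) & sc >= pwm$cutoff - 1e-12)
  data.frame(cpe_name = rep(pwm$name, length(hit)),
             start = anchored$rel_start + hit - 1L,
             score = sc[hit], stringsAsFactors = FALSE)
}

#' Functional window of a PWM
#' @param pwm A \code{cpe_pwm}.
#' @return Integer vector c(lo, hi), inclusive relative start positions.
#' @export
functional_window <- function(pwm) {
  c(pwm$expected_position - pwm$functional_halfwidth,
    pwm$expected_position + pwm$functional_halfwidth)
}

#' Scan a set of elements with a set of PWMs, honouring dependency rules
#'
#' Applies the partner rule: a CPE with \code{requires} set (DPE requires Inr)
#' reports hits only for elements that have at least one hit of the required
#' CPE inside the required CPE's functional window.
#'
#' @param anchored_list Named list of \code{anchored_seq} objects (names are
#'   element ids).
#' @param pwms Named list of \code{cpe_pwm} objects.
#' @return data.frame with columns element_id, cpe_name, start, score.
#' @export
scan_elements <- function(anchored_list, pwms) {
  ids <- names(anchored_list)
  if (is.null(ids)) ids <- paste0("el", seq_along(anchored_list))
  per_pwm <- lapply(pwms, function(pwm) {
    res <- lapply(seq_along(anchored_list), function(i) {
      h <- scan_pwm(anchored_list[[i]], pwm)
      if (nrow(h) > 0L) h$element_id <- ids[i]
      h
    })
    do.call(rbind, res[vapply(res, nrow, integer(1)) > 0L])
  })
  # dependency filtering
  for (nm in names(pwms)) {
    req <- pwms[[nm]]$requires
    if (is.null(req) || is.null(per_pwm[[nm]]) || nrow(per_pwm[[nm]]) == 0L) next
    if (!req %in% names(pwms)) stop("required CPE not in set: ", req)
    fw <- functional_window(pwms[[req]])
    reqhits <- per_pwm[[req]]
    ok_ids <- if (is.null(reqhits) || nrow(reqhits) == 0L) character(0) else
      unique(reqhits$element_id[reqhits$start >= fw[1] & reqhits$start <= fw[2]])
    per_pwm[[nm]] <- per_pwm[[nm]][per_pwm[[nm]]$element_id %in% ok_ids, ,
                                   drop = FALSE]
  }
  keep <- per_pwm[vapply(per_pwm, function(x) !is.null(x) && nrow(x) > 0L,
                         logical(1))]
  if (length(keep) == 0L) {
    return(data.frame(element_id = character(0), cpe_name = character(0),
                      start = integer(0), score = numeric(0)))
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out[, c("element_id", "cpe_name", "start", "score")]
}

#' Per-position occurrence counts of a CPE across elements
#'
#' counts[j] = number of distinct elements with a hit starting at relative
#' position j, over the scan range.
#'
#' @param hits Hit table from \code{\link{scan_elements}} (one CPE).
#' @param n_elements Total number of elements scanned.
#' @param range Inclusive relative position range, default c(-500, 200).
#' @return List with cpe_name, positions, counts, n_elements.
#' @export
positional_profile <- function(hits, n_elements, range = c(-500L, 200L)) {
  positions <- range[1]:range[2]
  counts <- integer(length(positions))
  if (nrow(hits) > 0L) {
    stopifnot(all(hits$start >= range[1] & hits$start <= range[2]))
    u <- unique(hits[, c("element_id", "start")])
    tab <- table(factor(u$start, levels = positions))
    counts <- as.integer(tab)
  }
  list(cpe_name = if (nrow(hits) > 0L) hits$cpe_name[1] else NA_character_,
       positions = positions, counts = counts, n_elements = n_elements)
}
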