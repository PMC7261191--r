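#' Dispersion index of a CAGE tag profile
#'
#' Tag-count-weighted standard deviation of initiation positions:
#' \code{s = sqrt( (1/c) sum_j (j - m)^2 x_j )} with \code{c = sum_j x_j} and
#' \code{m = (1/c) sum_j j x_j}, over positions within the capture window
#' (default -50..+50 relative to the TSS, same strand).
#'
#' @param positions Integer vector of tag positions j.
#' @param counts Non-negative tag counts x_j (same length).
#' @param window Inclusive capture window, default c(-50, 50).
#' @return Numeric s >= 0, or NA_real_ when no tags fall in the window
#'   (uninformative library).
#' @export
dispersion_index <- function(positions, counts, window = c(-50L, 50L)) {
  keep <- positions >= window[1] & positions <= window[2] & counts > 0
  if (!any(keep)) return(NA_real_)
  j <- positions[keep]; x <- counts[keep]
  cc <- sum(x)
  m <- sum(j * x) / cc
  sqrt(sum((j - m)^2 * x) / cc)
}

#' Sharp/broad classification from per-library dispersion indices
#'
#' The element is classified from the mean dispersion index over informative
#' libraries (those with at least one tag in the capture window): sharp when
#' the mean is <= threshold (inclusive), broad otherwise, unclassified when
#' fewer than \code{min_informative} libraries are informative (insufficient
#' CAGE tag coverage).
#'
#' @param s_values Per-library dispersion indices (NA = uninformative).
#' @param threshold Sharp/broad boundary, default 2.5.
#' @param min_informative Minimum informative libraries, default 1.
#' @return List with mean_dispersion, label ("sharp"|"broad"|"unclassified"),
#'   n_informative.
#' @export
classify_sharpness <- function(s_values, threshold = 2.5, min_informative = 1L) {
  s <- s_values[!is.na(s_values)]
  if (length(s) < min_informative) {
    return(list(mean_dispersion = NA_real_, label = "unclassified",
                n_informative = length(s)))
  }
  m <- mean(s)
  list(mean_dispersion = m,
       label = if (m <= threshold) "sharp" else "broad",
       n_informative = length(s))
}

#' Per-element, per-library dispersion indices from a tag table
#'
#' @param tags Tag table (element_id, library_id, strand, rel_position, count).
#' @param element_strand Named character vector: strand of each element's TSS;
#'   only tags on the same strand are counted. NULL = use all tags.
#' @param window Capture window, default c(-50, 50).
#' @return data.frame element_id, library_id, s.
#' @export
dispersion_table <- function(tags, element_strand = NULL, window = c(-50L, 50L)) {
  dt <- data.table::as.data.table(tags)
  if (!is.null(element_strand)) {
    dt <- dt[dt$strand == element_strand[dt$element_id], ]
  }
  dt <- dt[dt$rel_position >= window[1] & dt$rel_position <= window[2] &
             dt$count > 0, ]
  out <- dt[, list(s = dispersion_index(rel_position, count, window)),
            by = c("element_id", "library_id")]
  as.data.frame(out)
}

#' Sharp/broad classification for all elements
#'
#' @inheritParams dispersion_table
#' @param element_ids All element ids (elements with no informative library
#'   are reported unclassified).
#' @param threshold,min_informative See \code{\link{classify_sharpness}}.
#' @return data.frame element_id, mean_dispersion, label, n_informative.
#' @export
classify_elements <- function(tags, element_ids, element_strand = NULL,
                              window = c(-50L, 50L), threshold = 2.5,
                              min_informative = 1L) {
  st <- dispersion_table(tags, element_strand, window)
  res <- lapply(element_ids, function(id) {
    cl <- classify_sharpness(st$s[st$element_id == id], threshold,
                             min_informative)
    data.frame(element_id = id, mean_dispersion = cl$mean_dispersion,
               label = cl$label, n_informative = cl$n_informative,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-element, per-group log2 expression from CAGE tags
#'
#' Per library, counts are normalized to tags-per-million (over the library's
#' total tag count in the table); per group, the mean over member libraries is
#' taken of the windowed sum (positions -100..+100, same strand as the TSS);
#' the result is scaled by 1000 and transformed as log2(1 + x).
#'
#' @param tags Tag table.
#' @param library_map Library map (library_id, group, class).
#' @param element_ids All element ids (rows of the result).
#' @param element_strand Optional named strand vector for same-strand filtering.
#' @param window Summation window, default c(-100, 100).
#' @param scale Scale factor, default 1000.
#' @param classes Which library classes to include (default all in the map).
#' @return Numeric matrix, elements x groups.
#' @export
group_expression <- function(tags, library_map, element_ids,
                             element_strand = NULL, window = c(-100L, 100L),
                             scale = 1000, classes = NULL) {
  dt <- data.table::as.data.table(tags)
  lib_tot <- dt[, list(total = sum(count)), by = "library_id"]
  empty <- lib_tot$library_id[lib_tot$total == 0]
  if (length(empty) > 0L) {
    warning("excluding empty libraries: ", paste(empty, collapse = ", "))
  }
  if (!is.null(classes)) {
    library_map <- library_map[library_map$class %in% classes, ]
  }
  libs <- library_map$library_id[!library_map$library_id %in% empty]
  library_map <- library_map[library_map$library_id %in% libs, ]
  groups <- sort(unique(library_map$group))
  if (!is.null(element_strand)) {
    dt <- dt[dt$strand == element_strand[dt$element_id], ]
  }
  dt <- dt[dt$rel_position >= window[1] & dt$rel_position <= window[2] &
             dt$library_id %in% libs, ]
  dt <- merge(dt, lib_tot, by = "library_id")
  dt$tpm <- dt$count / dt$total * 1e6
  per_lib <- dt[, list(wsum = sum(tpm)), by = c("element_id", "library_id")]
  per_lib <- merge(per_lib,
                   data.table::as.data.table(library_map[, c("library_id", "group")]),
                   by = "library_id")
  # group mean must average over ALL member libraries, including those in
  # which the element has zero windowed tags
  nlib <- table(library_map$group)
  per_grp <- per_lib[, list(gsum = sum(wsum)), by = c("element_id", "group")]
  per_grp$gmean <- per_grp$gsum / as.numeric(nlib[per_grp$group])
  m <- matrix(0, nrow = length(element_ids), ncol = length(groups),
              dimnames = list(element_ids, groups))
  keep <- per_grp$element_id %in% element_ids
  m[cbind(per_grp$element_id[keep], per_grp$group[keep])] <- per_grp$gmean[keep]
  log2(1 + m * scale)
}

#' Tissue-specificity statistic tau
#'
#' \code{tau = sum_i (1 - x_i / max_j x_j) / (n - 1)}; 0 for uniform
#' (housekeeping) expression, 1 for single-group expression.
#'
#' @param x Non-negative per-group expression values, length n >= 2.
#' @return List with tau (NA when all values are zero), n_groups, defined flag.
#' @export
tau <- function(x) {
  n <- length(x)
  if (n < 2L) stop("tau needs at least 2 groups")
  if (any(x < 0)) stop("tau is defined for non-negative expression")
  mx <- max(x)
  if (mx == 0) return(list(tau = NA_real_, n_groups = n, defined = FALSE))
  list(tau = sum(1 - x / mx) / (n - 1), n_groups = n, defined = TRUE)
}

#' Select the top groups by total log expression over all elements
#'
#' @param expr Elements x groups matrix (log2 expression).
#' @param n_top Number of groups to keep (default 15); when fewer groups are
#'   available all are used with a warning.
#' @param Ties in column sums are broken lexicographically by group name.
#' @return Character vector of selected group names.
#' @export
select_top_groups <- function(expr, n_top = 15L) {
  sums <- colSums(expr)
  ord <- order(-sums, colnames(expr))
  if (ncol(expr) < n_top) {
    warning("only ", ncol(expr), " groups available; using all")
    n_top <- ncol(expr)
  }
  colnames(expr)[ord[seq_len(n_top)]]
}

#' Tau for every element over the selected top groups
#'
#' @param expr Elements x groups log-expression matrix.
#' @param groups Group subset (e.g. from \code{\link{select_top_groups}}).
#' @return data.frame element_id, tau, n_groups, defined.
#' @export
tau_table <- function(expr, groups = colnames(expr)) {
  sub <- expr[, groups, drop = FALSE]
  res <- apply(sub, 1, function(x) {
    t <- tau(x)
    c(t$tau, t$n_groups, t$defined)
  })
  data.frame(element_id = rownames(sub), tau = res[1, ],
             n_groups = as.integer(res[2, ]), defined = as.logical(res[3, ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcription directionality of a bidirectional enhancer
#'
#' R = reverse-strand tags at relative positions [-200, 0) of the enhancer
#' midpoint; F = forward-strand tags at [0, +200]. Directionality is
#' (F - R)/(F + R): 0 for balanced bidirectional transcription, +/-1 for
#' unidirectional.
#'
#' @param tags Tag rows for one enhancer pooled over libraries (strand,
#'   rel_position relative to the midpoint, count).
#' @param min_tags Minimum F + R for a defined value (default 1).
#' @return List with F, R, directionality (NA when F + R < min_tags), defined.
#' @export
directionality <- function(tags, min_tags = 1L) {
  Fcnt <- sum(tags$count[tags$strand == "+" &
                           tags$rel_position >= 0L & tags$rel_position <= 200L])
  Rcnt <- sum(tags$count[tags$strand == "-" &
                           tags$rel_position >= -200L & tags$rel_position < 0L])
  if (Fcnt + Rcnt < min_tags) {
    return(list(F = Fcnt, R = Rcnt, directionality = NA_real_, defined = FALSE))
  }
  list(F = Fcnt, R = Rcnt, directionality = (Fcnt - Rcnt) / (Fcnt + Rcnt),
       defined = TRUE)
}

#' Directionality for all enhancers in a tag table
#' @param tags Tag table with rel_position relative to enhancer midpoints.
#' @param element_ids All enhancer ids.
#' @param min_tags See \code{\link{directionality}}.
#' @return data.frame element_id, F, R, directionality, defined.
#' @export
directionality_table <- function(tags, element_ids, min_tags = 1L) {
  dt <- data.table::as.data.table(tags)
  fr <- dt[, list(
    Fc = sum(count[strand == "+" & rel_position >= 0L & rel_position <= 200L]),
    Rc = sum(count[strand == "-" & rel_position >= -200L & rel_position < 0L])),
    by = "element_id"]
  out <- data.frame(element_id = element_ids, F = 0L, R = 0L,
                    stringsAsFactors = FALSE)
  idx <- match(fr$element_id, out$element_id)
  ok <- !is.na(idx)
  out$F[idx[ok]] <- fr$Fc[ok]
  out$R[idx[ok]] <- fr$Rc[ok]
  tot <- out$F + out$R
  out$directionality <- ifelse(tot >= min_tags, (out$F - out$R) / tot, NA_real_)
  out$defined <- tot >= min_tags
  out
}
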