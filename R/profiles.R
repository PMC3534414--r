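#' Construct a time-course profile matrix
#'
#' Container for metabolite time-course measurements: a 3-dimensional array of
#' metabolite x time point x technical replicate, with ordered time points
#' split into a dehydration and a rehydration phase. Missing measurements are
#' \code{NA}.
#'
#' @param values numeric array \code{[metabolite, time, replicate]} with
#'   dimnames on the first dimension (metabolite IDs). Time points are taken
#'   in array order.
#' @param phase_split last time-point index of the dehydration phase
#'   (default 10; later time points are rehydration).
#' @param minutes optional numeric vector of sampling times (minutes), one
#'   per time point.
#' @return Object of class \code{profile_matrix} with elements \code{values},
#'   \code{metabolites}, \code{time_points} (data frame: index, phase,
#'   minutes).
#' @export
profile_matrix <- function(values, phase_split = 10, minutes = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_usage("values must be a 3-d array [metabolite, time, replicate]")
  m <- dim(values)[1]; k <- dim(values)[2]
  ids <- dimnames(values)[[1]]
  if (is.null(ids)) ids <- sprintf("M%03d", seq_len(m))
  dimnames(values)[[1]] <- ids
  if (phase_split < 0 || phase_split > k)
    stop_usage("phase_split outside the time-point range")
  tp <- data.frame(index = seq_len(k),
                   phase = factor(ifelse(seq_len(k) <= phase_split,
                                         "dehydration", "rehydration"),
                                  levels = c("dehydration", "rehydration")),
                   minutes = if (is.null(minutes)) NA_real_ else minutes)
  structure(list(values = values, metabolites = ids, time_points = tp,
                 phase_split = phase_split),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(paste0("profile_matrix: %d metabolites x %d time points x ",
                     "%d replicates (%d dehydration / %d rehydration)\n"),
              d[1], d[2], d[3], sum(x$time_points$phase == "dehydration"),
              sum(x$time_points$phase == "rehydration")))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' Sampling times of the dehydration/rehydration experiment
#'
#' Default sampling schedule in minutes for a 20-point experiment: ten
#' dehydration samples (60 to 1200 min, tun formation complete at the last)
#' followed by ten rehydration samples (0 to 270 min after re-adding water,
#' offset by the end of dehydration for a common axis).
#'
#' @return Numeric vector of length 20.
#' @export
default_sampling_minutes <- function() {
  dehydration <- c(60, 720, 900, 1020, 1080, 1110, 1140, 1170, 1185, 1200)
  rehydration <- 1200 + c(0, 5, 10, 15, 20, 60, 90, 150, 210, 270)
  c(dehydration, rehydration)
}

#' Read metabolite profiles from TSV
#'
#' Long format: columns \code{metabolite_id}, \code{time_point},
#' \code{replicate}, \code{value} (empty value = missing). Wide format: a
#' \code{metabolite_id} column followed by columns named \code{t<i>_r<j>}.
#' The format is auto-detected from the header.
#'
#' @param path TSV file path.
#' @param phase_split passed to [profile_matrix()].
#' @return A [profile_matrix()].
#' @export
read_profiles <- function(path, phase_split = 10) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop_usage("empty profile file: ", path)
  if (all(c("metabolite_id", "time_point", "replicate", "value") %in% names(df))) {
    ids <- unique(df$metabolite_id)
    k <- max(df$time_point); r <- max(df$replicate)
    arr <- array(NA_real_, dim = c(length(ids), k, r),
                 dimnames = list(ids, NULL, NULL))
    arr[cbind(match(df$metabolite_id, ids), df$time_point, df$replicate)] <-
      as.numeric(df$value)
    return(profile_matrix(arr, phase_split = phase_split))
  }
  wide_cols <- grep("^t[0-9]+_r[0-9]+$", names(df), value = TRUE)
  if (!"metabolite_id" %in% names(df) || length(wide_cols) == 0)
    stop_usage("unrecognized profile format in ", path,
               " (need long columns metabolite_id/time_point/replicate/value",
               " or wide columns t<i>_r<j>)")
  tp <- as.integer(sub("^t([0-9]+)_r[0-9]+$", "\\1", wide_cols))
  rep_ <- as.integer(sub("^t[0-9]+_r([0-9]+)$", "\\1", wide_cols))
  ids <- df$metabolite_id
  arr <- array(NA_real_, dim = c(length(ids), max(tp), max(rep_)),
               dimnames = list(ids, NULL, NULL))
  for (i in seq_along(wide_cols))
    arr[, tp[i], rep_[i]] <- as.numeric(df[[wide_cols[i]]])
  profile_matrix(arr, phase_split = phase_split)
}

#' Write metabolite profiles as long TSV
#'
#' @param pm a [profile_matrix()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(pm, path) {
  d <- dim(pm$values)
  idx <- expand.grid(m = seq_len(d[1]), t = seq_len(d[2]), r = seq_len(d[3]))
  df <- data.frame(metabolite_id = pm$metabolites[idx$m],
                   time_point = idx$t, replicate = idx$r,
                   value = pm$values[as.matrix(idx)])
  df <- df[order(df$metabolite_id, df$time_point, df$replicate), ]
  df$value[is.na(df$value)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep the highest-variance metabolite profiles
#'
#' Ranks metabolites by the variance of their per-time-point replicate means
#' and keeps the top \code{ceiling(fraction * m)}; ties are broken
#' deterministically by metabolite ID.
#'
#' @param pm a [profile_matrix()].
#' @param fraction fraction of metabolites to keep, in (0, 1].
#' @return A [profile_matrix()] with the selected metabolites.
#' @export
top_variance <- function(pm, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_usage("fraction must be in (0, 1]")
  means <- apply(pm$values, c(1, 2), mean, na.rm = TRUE)
  v <- apply(means, 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  keep_n <- ceiling(fraction * length(pm$metabolites))
  ord <- order(-v, pm$metabolites)
  keep <- sort(ord[seq_len(keep_n)])
  profile_matrix(pm$values[keep, , , drop = FALSE],
                 phase_split = pm$phase_split,
                 minutes = pm$time_points$minutes)
}

# groups (list of replicate vectors per time point) for one metabolite
profile_groups <- function(pm, metabolite) {
  vals <- pm$values[metabolite, , , drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  lapply(seq_len(nrow(vals)), function(t) {
    x <- vals[t, ]
    x[!is.na(x)]
  })
}
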