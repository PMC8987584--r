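#' Marker trajectory field
#'
#' Per-marker 3D coordinate histories on a shared, strictly increasing
#' time grid, as produced by neutral-density-target (NDT) tracking in
#' cadaver head impacts or by [make_marker_field()].
#'
#' @param time time grid (ms), strictly increasing.
#' @param positions numeric array `[n_time, n_markers, 3]` (mm).
#' @param ids marker labels (default `m1..mN`).
#' @return object of class `marker_field`.
#' @export
marker_field <- function(time, positions, ids = NULL) {
  time <- as.numeric(time)
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  positions <- unclass(positions)
  d <- dim(positions)
  if (length(d) != 3L || d[1] != length(time) || d[3] != 3L)
    stop("positions must be an [n_time, n_markers, 3] array")
  if (d[2] < 3L) stop("need at least 3 markers to form a triad")
  if (anyNA(positions)) stop("positions must not contain missing samples")
  if (is.null(ids)) ids <- paste0("m", seq_len(d[2]))
  stopifnot(length(ids) == d[2])
  structure(list(time = time, positions = positions, ids = ids),
            class = "marker_field")
}

#' Read a marker field from CSV
#'
#' Expects a `time_ms` column followed by `x_<id>`, `y_<id>`, `z_<id>`
#' column triples per marker; `#`-prefixed lines are metadata.
#'
#' @param path CSV file path.
#' @return a `marker_field`.
#' @export
read_marker_field <- function(path) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_ms" %in% names(df)) stop("marker CSV must have a time_ms column")
  xs <- grep("^x_", names(df), value = TRUE)
  ids <- sub("^x_", "", xs)
  if (length(ids) == 0L) stop("marker CSV must have x_<id>/y_<id>/z_<id> columns")
  pos <- array(NA_real_, c(nrow(df), length(ids), 3L))
  for (j in seq_along(ids)) {
    for (k in 1:3) {
      cn <- paste0(c("x_", "y_", "z_")[k], ids[j])
      if (!cn %in% names(df)) stop("missing column: ", cn)
      pos[, j, k] <- df[[cn]]
    }
  }
  marker_field(df$time_ms, pos, ids)
}

#' Write a marker field to CSV
#'
#' @param markers a `marker_field`.
#' @param path output path.
#' @param meta named character vector written as `#` metadata lines.
#' @export
write_marker_field <- function(markers, path, meta = character()) {
  ids <- markers$ids
  df <- data.frame(time_ms = markers$time)
  for (j in seq_along(ids)) {
    df[[paste0("x_", ids[j])]] <- markers$positions[, j, 1]
    df[[paste0("y_", ids[j])]] <- markers$positions[, j, 2]
    df[[paste0("z_", ids[j])]] <- markers$positions[, j, 3]
  }
  write_timeseries(df, path, meta = c(meta, units = "time ms, length mm"))
}

#' Marker triad definitions
#'
#' Triples of marker ids forming the triangles ("null shells") whose
#' in-plane Green strain is extracted. The default cluster layout uses 7
#' markers forming 12 triads.
#'
#' @param triads list of character or integer id-triples.
#' @param reference_time index of the time sample taken as the undeformed
#'   configuration (default 1, the initial marker locations).
#' @return object of class `triad_set`.
#' @export
triad_set <- function(triads, reference_time = 1L) {
  stopifnot(length(triads) >= 1L,
            all(vapply(triads, length, integer(1)) == 3L))
  structure(list(triads = triads,
                 reference_time = as.integer(reference_time)),
            class = "triad_set")
}

#' Default 12-triad layout over a 7-marker cluster
#'
#' @return a `triad_set` of 12 index-triples over markers 1..7 (six outer
#'   markers in two tiers plus a central marker).
#' @export
default_triads <- function() {
  triad_set(list(c(1, 2, 3), c(4, 5, 6),
                 c(1, 2, 7), c(2, 3, 7), c(1, 3, 7),
                 c(4, 5, 7), c(5, 6, 7), c(4, 6, 7),
                 c(1, 4, 7), c(2, 5, 7), c(3, 6, 7), c(1, 5, 7)))
}

tri_area <- function(e1, e2) 0.5 * sqrt(sum(crossprod3(e1, e2)^2))
crossprod3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

# 2D coordinates of a triangle's two edge vectors in its own plane
plane_coords <- function(e1, e2) {
  b1 <- e1 / sqrt(sum(e1^2))
  w <- e2 - sum(e2 * b1) * b1
  b2 <- w / sqrt(sum(w^2))
  matrix(c(sum(e1 * b1), 0, sum(e2 * b1), sum(e2 * b2)), 2, 2)
}

#' Green maximum principal strain histories from marker triads
#'
#' For each triad and time sample, builds the in-plane 2D deformation
#' gradient mapping the reference triangle edges onto the current edges,
#' forms the Green-Lagrange strain `E = (F^T F - I)/2`, and reports the
#' larger principal value, clipped at 0 (maximum principal strain is
#' reported as positive; pure contraction yields 0). Strain is evaluated
#' in the instantaneous triangle plane, so out-of-plane motion enters
#' only through edge-length changes. Per-triad histories are averaged
#' arithmetically across triads.
#'
#' Samples where the current triangle is degenerate (area below
#' `1e-6` of the reference area) are excluded from the average and
#' counted in `n_excluded`, with a warning.
#'
#' @param markers a [marker_field()].
#' @param triads a [triad_set()]; default [default_triads()].
#' @return object of class `strain_history`: fields `time` (ms),
#'   `per_triad` (matrix `[n_time, n_triads]`), `gmps_avg`, `n_excluded`.
#' @examples
#' mf <- make_marker_field(synthetic_spec(seed = 1, kind = "marker_field",
#'                         parameters = list(peak_gmps = 0.05,
#'                                           noise_sd_mm = 0)))
#' sh <- triad_gmps(mf$markers)
#' max(sh$gmps_avg)
#' @export
triad_gmps <- function(markers, triads = default_triads()) {
  stopifnot(inherits(markers, "marker_field"), inherits(triads, "triad_set"))
  ids <- markers$ids
  idx <- lapply(triads$triads, function(tr) {
    if (is.character(tr)) match(tr, ids) else as.integer(tr)
  })
  if (anyNA(unlist(idx))) stop("triad refers to unknown marker id")
  nt <- length(markers$time)
  k <- length(idx)
  ref_i <- triads$reference_time
  per <- matrix(NA_real_, nt, k)
  n_excluded <- 0L
  for (j in seq_len(k)) {
    tr <- idx[[j]]
    P <- markers$positions[ref_i, tr, , drop = TRUE]  # 3 x 3 (vertex x coord)
    U1 <- P[2, ] - P[1, ]; U2 <- P[3, ] - P[1, ]
    ref_area <- tri_area(U1, U2)
    if (ref_area < 1e-12)
      stop("degenerate reference triangle in triad ", j)
    Ref2 <- plane_coords(U1, U2)
    for (i in seq_len(nt)) {
      p <- markers$positions[i, tr, , drop = TRUE]
      v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
      if (tri_area(v1, v2) < 1e-6 * ref_area) {
        n_excluded <- n_excluded + 1L
        next
      }
      F2 <- plane_coords(v1, v2) %*% solve(Ref2)
      E <- 0.5 * (crossprod(F2) - diag(2))
      per[i, j] <- max(0, max(eigen(E, symmetric = TRUE,
                                    only.values = TRUE)$values))
    }
  }
  if (n_excluded > 0L)
    warning(n_excluded, " degenerate triad sample(s) excluded from average")
  structure(list(time = markers$time, per_triad = per,
                 gmps_avg = rowMeans(per, na.rm = TRUE),
                 n_excluded = n_excluded),
            class = "strain_history")
}

#' Strain rate and strain x strain-rate channels of a strain history
#'
#' Differentiates the averaged Green MPS history by central differences
#' (one-sided at the ends, local spacing on non-uniform grids), converts
#' to 1/s (time grid is in ms), and forms the pointwise
#' `MPS x MPSR` product channel.
#'
#' @param history a `strain_history` (or `data.frame(time, gmps_avg)`).
#' @return the history augmented with `mpsr` (1/s), `product` (1/s), and
#'   peaks `peak_mps`, `peak_mpsr`, `peak_product`.
#' @export
mps_rate <- function(history) {
  if (is.data.frame(history))
    history <- structure(list(time = history[[1]],
                              gmps_avg = history[[2]]),
                         class = "strain_history")
  stopifnot(inherits(history, "strain_history"))
  t <- history$time; y <- history$gmps_avg
  n <- length(t)
  if (n < 3L) stop("need at least 3 time samples to differentiate")
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  for (i in 2:(n - 1)) d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  d <- d * 1000  # 1/ms -> 1/s
  history$mpsr <- d
  history$product <- y * d
  history$peak_mps <- max(y, na.rm = TRUE)
  history$peak_mpsr <- max(d, na.rm = TRUE)
  history$peak_product <- max(history$product, na.rm = TRUE)
  history
}

#' Mean of the k largest per-element peaks
#'
#' Peak response for a structure is conventionally taken as the average
#' of the highest values from the top `k` elements (default 10) rather
#' than a single extreme element, to damp numerical artifacts from
#' poorly shaped elements.
#'
#' @param values per-element peak values (non-empty numeric).
#' @param k number of top elements to average (capped at the list length
#'   with a warning).
#' @return scalar mean of the `k` largest values.
#' @export
topk_peak <- function(values, k = 10L) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("topk_peak: empty value list")
  if (k < 1L) stop("k must be >= 1")
  if (k > length(values)) {
    warning("k = ", k, " capped at list length ", length(values))
    k <- length(values)
  }
  mean(sort(values, decreasing = TRUE)[seq_len(k)])
}

#' Diffuse brain injury reference report
#'
#' Compares per-structure peak MPS, MPSR, and MPS x MPSR against the
#' packaged reference levels: the low-risk (AIS 2 concussion) reference
#' (MPS 0.65, MPSR 61.52/s, MPS x MPSR 22.43/s) and the AIS 4+ diffuse
#' brain injury reference (0.74, 213/s, 107/s). No fitted risk curve
#' exists for diffuse injury, so flags are qualitative; comparisons are
#' inclusive (a peak exactly at a reference level is flagged at it).
#'
#' @param histories named list of `strain_history` objects (one per
#'   structure, e.g. subcortical white matter, corpus callosum,
#'   brainstem); [mps_rate()] is applied if the rate channels are absent.
#' @return data.frame with one row per structure plus an `average` row,
#'   columns `peak_mps`, `peak_mpsr`, `peak_product` and the
#'   corresponding flags (`"below low-risk reference"`,
#'   `"at/above low-risk reference"`, `"at/above AIS 4+ reference"`).
#' @export
diffuse_injury_report <- function(histories) {
  if (inherits(histories, "strain_history")) histories <- list(histories)
  if (length(histories) == 0L) stop("diffuse_injury_report: empty input")
  if (is.null(names(histories)) || any(names(histories) == ""))
    names(histories) <- paste0("structure_", seq_along(histories))
  ref <- diffuse_reference()
  rows <- lapply(histories, function(h) {
    if (is.null(h$mpsr)) h <- mps_rate(h)
    c(peak_mps = h$peak_mps, peak_mpsr = h$peak_mpsr,
      peak_product = h$peak_product)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- rbind(tab, average = colMeans(tab))
  flag1 <- function(x, lo, hi) {
    # inclusive comparisons with a 1e-9 relative guard so a peak computed
    # to sit exactly at a reference level is flagged at it
    if (x >= hi * (1 - 1e-9)) "at/above AIS 4+ reference"
    else if (x >= lo * (1 - 1e-9)) "at/above low-risk reference"
    else "below low-risk reference"
  }
  tab$flag_mps <- vapply(tab$peak_mps, flag1,
                         character(1), ref$low_risk$mps, ref$ais4plus$mps)
  tab$flag_mpsr <- vapply(tab$peak_mpsr, flag1,
                          character(1), ref$low_risk$mpsr, ref$ais4plus$mpsr)
  tab$flag_product <- vapply(tab$peak_product, flag1, character(1),
                             ref$low_risk$product, ref$ais4plus$product)
  tab
}
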