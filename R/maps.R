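#' Construct a helix-configuration metric map
#'
#' @param tau_bar,tau_diff grid vectors (degrees, strictly increasing).
#' @param values matrix of metric values, `length(tau_bar)` x
#'   `length(tau_diff)`; NA marks masked (failed) nodes.
#' @param metric metric name.
#' @export
helix_map <- function(tau_bar, tau_diff, values, metric = "metric") {
  values <- as.matrix(values)
  if (nrow(values) != length(tau_bar) || ncol(values) != length(tau_diff))
    stop_lv("value matrix dimensions do not match the grids")
  if (any(diff(tau_bar) <= 0) || (length(tau_diff) > 1 && any(diff(tau_diff) <= 0)))
    stop_lv("grids must be strictly increasing")
  if (any(range(c(tau_bar, tau_diff)) < -90 - 1e-9) ||
      any(range(c(tau_bar, tau_diff)) > 180 + 1e-9))
    warning("grid extends outside the swept range [-90, 180] degrees")
  structure(list(tau_bar = tau_bar, tau_diff = tau_diff, values = values,
                 mask = is.na(values), metric = metric),
            class = "helix_map")
}

#' Continuous interpolant of a helix map
#'
#' Tensor-product natural cubic spline through the grid nodes (masked nodes
#' are skipped row-wise); reproduces node values exactly.
#'
#' @param map a [helix_map()].
#' @return function(tau_bar, tau_diff) evaluating the interpolant.
#' @export
map_interpolant <- function(map) {
  tb <- map$tau_bar; td <- map$tau_diff
  spline1 <- function(x, y, xout) {
    ok <- !is.na(y)
    if (sum(ok) == 0) return(rep(NA_real_, length(xout)))
    if (sum(ok) == 1) return(rep(y[ok], length(xout)))
    splinefun(x[ok], y[ok], method = "natural")(xout)
  }
  function(tau_bar, tau_diff) {
    mapply(function(b, d) {
      if (length(td) == 1) return(spline1(tb, map$values[, 1], b))
      rowvals <- vapply(seq_along(tb),
                        function(i) spline1(td, map$values[i, ], d), numeric(1))
      spline1(tb, rowvals, b)
    }, tau_bar, tau_diff)
  }
}

#' Locate the optimum of a helix map
#'
#' Continuous optimization of the spline interpolant within the grid hull,
#' multi-started from the best grid nodes; sets a boundary flag when the
#' optimum lies on the hull edge.
#'
#' @param map a [helix_map()].
#' @param criterion one of `max_stroke_work`, `max_myofiber_stress`,
#'   `min_deform_burden`, `min_strain_variance`, or plain `max` / `min`.
#' @return list `tau_bar`, `tau_diff`, `value`, `direction`, `boundary`.
#' @export
find_optimal_point <- function(map, criterion = "max") {
  direction <- if (grepl("^max", criterion)) "max" else "min"
  vals <- map$values
  rng <- range(vals, na.rm = TRUE)
  if (diff(rng) < 1e-12 * max(1, abs(mean(vals, na.rm = TRUE))))
    stop_lv("flat map: no distinct optimum")
  f <- map_interpolant(map)
  sgn <- if (direction == "max") -1 else 1
  obj <- function(x) sgn * f(x[1], x[2])
  starts <- head(which(!is.na(vals))[order(sgn * vals[!is.na(vals)])], 3)
  lb <- c(min(map$tau_bar), min(map$tau_diff))
  ub <- c(max(map$tau_bar), max(map$tau_diff))
  best <- NULL
  for (k in starts) {
    i <- (k - 1) %% nrow(vals) + 1
    j <- (k - 1) %/% nrow(vals) + 1
    x0 <- c(map$tau_bar[i], map$tau_diff[j])
    res <- optim(x0, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                 control = list(factr = 1e4))
    if (is.null(best) || res$value < best$value) best <- res
  }
  tol <- 1e-4 * max(ub - lb)
  on_edge <- any(abs(best$par - lb) < tol) || any(abs(best$par - ub) < tol)
  list(tau_bar = best$par[1], tau_diff = best$par[2],
       value = sgn * best$value, direction = direction, boundary = on_edge)
}

#' Sweep a metric evaluator over a helix-configuration grid
#'
#' Runs `evaluate(helix_config)` at every grid node, masking failed nodes
#' (recorded, and an error if more than the tolerated fraction fail), and
#' returns one [helix_map()] per metric.
#'
#' @param evaluate function taking a [helix_config()] and returning a named
#'   numeric list/vector of metrics.
#' @param tau_bar,tau_diff grid vectors in degrees.
#' @param metrics metric names to extract (default: all returned).
#' @param max_fail_frac maximum tolerated fraction of failed nodes.
#' @param progress print per-node progress.
#' @return named list of `helix_map`s plus attribute `failures`.
#' @export
sweep_helix_map <- function(evaluate, tau_bar, tau_diff, metrics = NULL,
                            max_fail_frac = 0.2, progress = FALSE) {
  nb <- length(tau_bar); nd <- length(tau_diff)
  results <- vector("list", nb * nd)
  fails <- character(0)
  for (j in seq_len(nd)) for (i in seq_len(nb)) {
    cfgp <- helix_config(tau_bar[i], tau_diff[j])
    r <- tryCatch(evaluate(cfgp), error = function(e) e)
    k <- (j - 1) * nb + i
    if (inherits(r, "error")) {
      fails <- c(fails, sprintf("(%g, %g): %s", tau_bar[i], tau_diff[j],
                                conditionMessage(r)))
      results[[k]] <- NULL
    } else results[[k]] <- r
    if (progress)
      message(sprintf("helix (%g, %g): %s", tau_bar[i], tau_diff[j],
                      if (inherits(r, "error")) "FAILED" else "ok"))
  }
  nfail <- length(fails)
  if (nfail / (nb * nd) > max_fail_frac)
    stop_lv("%d of %d grid nodes failed:\n%s", nfail, nb * nd,
            paste(fails, collapse = "\n"))
  metrics <- metrics %||% names(results[[which(!vapply(results, is.null, TRUE))[1]]])
  maps <- lapply(metrics, function(m) {
    vals <- matrix(NA_real_, nb, nd)
    for (j in seq_len(nd)) for (i in seq_len(nb)) {
      r <- results[[(j - 1) * nb + i]]
      if (!is.null(r)) vals[i, j] <- as.numeric(r[[m]])
    }
    helix_map(tau_bar, tau_diff, vals, metric = m)
  })
  names(maps) <- metrics
  attr(maps, "failures") <- fails
  maps
}

gaussian_window <- function(radius = 1, sigma = 1) {
  x <- -radius:radius
  w <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  w / sum(w)
}

# windowed local moments with border renormalization
local_filter <- function(m, w) {
  r <- (nrow(w) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- max(1, i - r):min(nrow(m), i + r)
    jj <- max(1, j - r):min(ncol(m), j + r)
    ww <- w[ii - i + r + 1, jj - j + r + 1, drop = FALSE]
    out[i, j] <- sum(ww * m[ii, jj]) / sum(ww)
  }
  out
}

#' Structural similarity index between two helix maps
#'
#' Standard SSIM with Gaussian windowing (3x3 nodes) and default
#' stabilization constants, computed on the pair after joint min-max
#' normalization; 1 for identical maps.
#'
#' @param a,b [helix_map()]s on the same grid.
#' @return mean SSIM score in [-1, 1].
#' @export
map_ssim <- function(a, b) {
  if (!isTRUE(all.equal(a$tau_bar, b$tau_bar)) ||
      !isTRUE(all.equal(a$tau_diff, b$tau_diff)))
    stop_lv("maps are on different grids")
  x <- a$values; y <- b$values
  if (anyNA(x) || anyNA(y)) stop_lv("SSIM requires fully evaluated maps")
  lo <- min(x, y); hi <- max(x, y)
  if (hi > lo) { x <- (x - lo) / (hi - lo); y <- (y - lo) / (hi - lo) }
  C1 <- 0.01^2; C2 <- 0.03^2
  w <- gaussian_window(1, 1)
  mx <- local_filter(x, w); my <- local_filter(y, w)
  vx <- local_filter(x^2, w) - mx^2
  vy <- local_filter(y^2, w) - my^2
  cxy <- local_filter(x * y, w) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Write a helix map to CSV (long format) and JSON
#' @param map a [helix_map()].
#' @param path_csv,path_json output paths (NULL to skip either).
#' @param optimum optional [find_optimal_point()] result to embed.
#' @export
write_helix_map <- function(map, path_csv = NULL, path_json = NULL,
                            optimum = NULL) {
  if (!is.null(path_csv)) {
    df <- expand.grid(tau_bar = map$tau_bar, tau_diff = map$tau_diff)
    df$value <- as.vector(map$values)
    df$metric <- map$metric
    write.csv(df, path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(metric = map$metric, tau_bar = map$tau_bar,
           tau_diff = map$tau_diff, values = map$values,
           optimum = optimum),
      path_json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(map)
}
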