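# Configuration metrics: local open area (LOA) enclosed by a spline through
# the strut-end apex points, strut-centre deviation e_c, relative LOA
# deviation e_LOA, and landing-section summaries.

#' Local open area enclosed by strut-end apex points
#'
#' Fits the least-squares plane of the apex cloud (two dominant principal
#' directions of the centred points), projects the points onto it, closes
#' them with a periodic cubic spline under chord-length parameterization,
#' and integrates the enclosed area by Green's theorem on a dense sampling
#' of the spline. The result is invariant under rigid-body transforms of
#' the input. `mode = "polygon"` uses the shoelace formula on the projected
#' polygon instead (cross-check mode).
#'
#' @param apex_points Numeric matrix (>= 3 rows, 3 columns) of ordered apex
#'   coordinates, mm.
#' @param mode `"spline"` (default) or `"polygon"`.
#' @param n_dense Dense sampling count for the spline integration.
#' @return Enclosed area, mm^2.
#' @export
local_open_area <- function(apex_points, mode = c("spline", "polygon"),
                            n_dense = 2048) {
  mode <- match.arg(mode)
  p <- as.matrix(apex_points)
  if (ncol(p) != 3 || nrow(p) < 3)
    stop("apex_points must be an n x 3 matrix with n >= 3")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("apex points are collinear; no enclosed area")
  # project onto the two dominant principal directions
  xy <- q %*% sv$v[, 1:2]

  if (mode == "polygon") return(abs(shoelace(xy[, 1], xy[, 2])))

  if (polygon_self_intersects(xy))
    stop("projected apex loop is self-intersecting")
  # closed chord-length parameterization
  n <- nrow(xy)
  xyc <- rbind(xy, xy[1, , drop = FALSE])
  tt <- c(0, cumsum(sqrt(rowSums(diff(xyc)^2))))
  if (tt[length(tt)] <= 0) stop("degenerate apex loop")
  ts <- seq(0, tt[length(tt)], length.out = n_dense + 1)
  xs <- stats::spline(tt, xyc[, 1], method = "periodic", xout = ts)$y
  ys <- stats::spline(tt, xyc[, 2], method = "periodic", xout = ts)$y
  abs(shoelace(xs, ys))
}

shoelace <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

# O(n^2) segment intersection test on the closed polygon (n is small)
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(FALSE)
  seg <- function(i) list(a = xy[i, ], b = xy[if (i == n) 1 else i + 1, ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
    (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(s1, s2) {
    d1 <- cross2(s2$a, s2$b, s1$a); d2 <- cross2(s2$a, s2$b, s1$b)
    d3 <- cross2(s1$a, s1$b, s2$a); d4 <- cross2(s1$a, s1$b, s2$b)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) <= 1 || (i == 1 && j == n)) next
    if (intersects(seg(i), seg(j))) return(TRUE)
  }
  FALSE
}

#' Strut-centre deviation between two configurations
#'
#' Euclidean distance between the apex-point centroids of the simulated and
#' reference strut end. A metric: symmetric, zero iff the centroids
#' coincide, and satisfying the triangle inequality.
#'
#' @param sim,ref Numeric matrices (n x 3) of apex points, or lists with a
#'   `label` attribute. When both carry labels they must match.
#' @return Centre deviation e_c, mm.
#' @export
strut_centre_deviation <- function(sim, ref) {
  ls <- attr(sim, "label"); lr <- attr(ref, "label")
  if (!is.null(ls) && !is.null(lr) && !identical(ls, lr))
    stop("strut-end label mismatch: ", ls, " vs ", lr)
  cs <- colMeans(as.matrix(sim)); cr <- colMeans(as.matrix(ref))
  sqrt(sum((cs - cr)^2))
}

#' Per-section summary of per-end values
#'
#' Aggregates per-strut-end values into landing-section rows with mean,
#' population standard deviation (n denominator) and range.
#'
#' @param values Named numeric vector (names are strut-end labels).
#' @param section_map Named character vector mapping every label to a
#'   section.
#' @return Data frame with columns `section, n, mean, sd, min, max`.
#' @export
section_summary <- function(values, section_map) {
  labs <- names(values)
  if (is.null(labs) || any(!labs %in% names(section_map)))
    stop("every end must be assigned to exactly one section")
  sec <- section_map[labs]
  out <- do.call(rbind, lapply(split(values, sec), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = sqrt(mean((v - mean(v))^2)),   # population SD
               min = min(v), max = max(v))
  }))
  out <- cbind(section = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Default landing-section assignment of strut ends
#'
#' Struts 1-2 and the proximal end of strut 3 land in the healthy aorta;
#' D3 through P5 in the entry-tear region; D5 and all more distal ends in
#' the dissection section.
#'
#' @param n_struts Number of struts (default 9).
#' @return Named character vector label -> section.
#' @export
default_section_map <- function(n_struts = 9) {
  labs <- c(rbind(paste0("P", 1:n_struts), paste0("D", 1:n_struts)))
  # order along the device: P1 D1 P2 D2 ...
  idx <- seq_along(labs)
  sec <- ifelse(idx <= which(labs == "P3"), "healthy",
                ifelse(idx <= which(labs == "P5"), "entry_tear",
                       "dissection"))
  stats::setNames(sec, labs)
}

#' Validation report: e_LOA and e_c per end and per section
#'
#' Compares simulated against reference strut-end configurations:
#' per end the relative open-area deviation
#' `e_LOA = 100 * (LOA_sim - LOA_ref) / LOA_ref` (percent) and the centre
#' deviation `e_c` (mm); per landing section the mean, population SD and
#' range of each. An optional rigid pre-alignment transform
#' (`list(R, t)`: rotation matrix and translation) is applied to the
#' simulated points first.
#'
#' @param sim,ref Named lists of apex-point matrices (labels as names).
#' @param section_map Named label -> section map; default
#'   [default_section_map()].
#' @param align Optional rigid transform applied to `sim`.
#' @return An object of class `validation_report`: `per_end` data frame and
#'   `per_section` (list of two data frames, `e_loa` and `e_c`).
#' @export
validation_report <- function(sim, ref, section_map = default_section_map(),
                              align = NULL) {
  labs <- intersect(names(sim), names(ref))
  if (length(labs) == 0) stop("no shared strut-end labels")
  if (!is.null(align))
    sim <- lapply(sim, function(p) sweep(as.matrix(p) %*% t(align$R), 2,
                                         -align$t))
  per_end <- do.call(rbind, lapply(labs, function(lb) {
    loa_s <- local_open_area(sim[[lb]])
    loa_r <- local_open_area(ref[[lb]])
    data.frame(label = lb,
               loa_sim = loa_s, loa_ref = loa_r,
               e_loa = 100 * (loa_s - loa_r) / loa_r,
               e_c = strut_centre_deviation(sim[[lb]], ref[[lb]]),
               section = unname(section_map[lb]),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    per_end = per_end,
    per_section = list(
      e_loa = section_summary(stats::setNames(per_end$e_loa, per_end$label),
                              section_map),
      e_c = section_summary(stats::setNames(per_end$e_c, per_end$label),
                            section_map))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (per landing section):\n  e_LOA (%):\n")
  print(x$per_section$e_loa, row.names = FALSE)
  cat("  e_c (mm):\n")
  print(x$per_section$e_c, row.names = FALSE)
  invisible(x)
}

#' Open-area jumps at the landing-section borders
#'
#' Absolute LOA differences across the two section borders (strut 3:
#' P3 vs D3, and strut 5: P5 vs D5).
#'
#' @param loa Named numeric vector of open areas (mm^2) containing at least
#'   `P3, D3, P5, D5`.
#' @return Named numeric vector `c(P3_D3 = ..., P5_D5 = ...)`, mm^2.
#' @export
loa_border_jump <- function(loa) {
  need <- c("P3", "D3", "P5", "D5")
  if (!all(need %in% names(loa)))
    stop("missing strut ends: ", paste(setdiff(need, names(loa)), collapse = ", "))
  c(P3_D3 = abs(loa[["D3"]] - loa[["P3"]]),
    P5_D5 = abs(loa[["D5"]] - loa[["P5"]]))
}
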