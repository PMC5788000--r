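#' Build a synthetic tree description
#'
#' Places fruiting units (FUs) as ellipsoids inside a crown envelope, attaches
#' them to four scaffold axes rooted at the trunk, and distributes the crop
#' load over the FUs. One additional unit represents the whole-tree water
#' sprout pool (a leafy, fruitless unit near the crown top); its leaf area
#' follows the water-sprout compartment dry mass during a simulation.
#'
#' Coordinates are tree-local Cartesian in metres, z up, collar at the origin.
#'
#' @param seed integer seed (placement is deterministic given it).
#' @param n_fu number of fruiting units (water-sprout unit added on top).
#' @param n_fruits total crop load distributed over the FUs.
#' @param crown_radius,crown_base,crown_top crown envelope geometry (m).
#' @param fu_semiaxes nominal FU ellipsoid semi-axes (m), jittered per FU.
#' @param n_sprouts number of water sprouts carried by the whole-tree
#'   water-sprout unit.
#' @param params parameter set (for initial dry masses and SLA).
#' @return object of class \code{orchard_tree}: list with \code{fu} (data
#'   frame: id, x, y, z, ax, ay, az, leaf_area, n_fruits, n_shoots,
#'   axis_id, is_ws),
#'   \code{axes} (data frame: id, parent, x, y, z of distal node, length,
#'   diameter, fu_id or NA), and \code{spacing}.
#' @examples
#' tr <- synthetic_tree(1, n_fu = 8, n_fruits = 28)
#' tr
#' @export
synthetic_tree <- function(seed, n_fu = 80, n_fruits = 280,
                           crown_radius = 1.6, crown_base = 0.8,
                           crown_top = 3.4,
                           fu_semiaxes = c(0.30, 0.30, 0.25),
                           n_sprouts = 100,
                           params = default_params()) {
  set.seed(as.integer(seed))
  n <- n_fu
  # FU centroids: uniform in the crown ellipsoid envelope
  zc <- (crown_base + crown_top) / 2
  zr <- (crown_top - crown_base) / 2
  pts <- matrix(NA_real_, n, 3)
  got <- 0
  while (got < n) {
    m <- 4 * (n - got)
    x <- stats::runif(m, -1, 1); y <- stats::runif(m, -1, 1)
    z <- stats::runif(m, -1, 1)
    keep <- x^2 + y^2 + z^2 <= 1
    take <- min(sum(keep), n - got)
    if (take > 0) {
      idx <- which(keep)[seq_len(take)]
      pts[got + seq_len(take), ] <- cbind(x[idx] * crown_radius,
                                          y[idx] * crown_radius,
                                          zc + z[idx] * zr)
      got <- got + take
    }
  }
  jit <- matrix(stats::runif(3 * n, 0.85, 1.15), n, 3)
  semi <- sweep(jit, 2, fu_semiaxes, "*")

  # shoot and crop counts per FU
  n_shoots <- sample(5:12, n, replace = TRUE)
  nf <- as.integer(stats::rmultinom(1, n_fruits, rep(1, n)))
  leafy0 <- params$initial$leafy_dm            # g per shoot
  la <- params$growth$sla * leafy0 * n_shoots

  fu <- data.frame(
    id = seq_len(n), x = pts[, 1], y = pts[, 2], z = pts[, 3],
    ax = semi[, 1], ay = semi[, 2], az = semi[, 3],
    leaf_area = la, n_fruits = nf, n_shoots = n_shoots,
    axis_id = NA_integer_, is_ws = FALSE
  )
  # water-sprout unit: crown top, starts with (near-)zero leaf area;
  # its n_shoots is the number of sprouts on the tree
  ws <- data.frame(id = n + 1L, x = 0, y = 0, z = crown_top - 0.2,
                   ax = 0.6, ay = 0.6, az = 0.5,
                   leaf_area = 0, n_fruits = 0L, n_shoots = n_sprouts,
                   axis_id = NA_integer_, is_ws = TRUE)
  fu <- rbind(fu, ws)

  # axes: trunk (1), four scaffolds (2-5), one axis per unit
  trunk_top <- c(0, 0, crown_base)
  sc_dir <- cbind(cos(pi / 4 + pi / 2 * 0:3), sin(pi / 4 + pi / 2 * 0:3), 0.9)
  sc_end <- sweep(sc_dir * 1.0, 2, trunk_top, "+")
  axes <- data.frame(
    id = 1:5,
    parent = c(0L, 1L, 1L, 1L, 1L),
    x = c(trunk_top[1], sc_end[, 1]), y = c(trunk_top[2], sc_end[, 2]),
    z = c(trunk_top[3], sc_end[, 3]),
    length = c(crown_base, rep(sqrt(sum((sc_dir[1, ] * 1.0)^2)), 4)),
    diameter = c(0.10, rep(0.05, 4)),
    fu_id = NA_integer_
  )
  # attach each unit to its nearest scaffold end
  for (i in seq_len(nrow(fu))) {
    d2 <- colSums((t(as.matrix(axes[2:5, c("x", "y", "z")])) -
                     as.numeric(fu[i, c("x", "y", "z")]))^2)
    sc <- 1L + which.min(d2)
    len <- max(0.15, sqrt(min(d2)))
    axes <- rbind(axes, data.frame(
      id = nrow(axes) + 1L, parent = sc,
      x = fu$x[i], y = fu$y[i], z = fu$z[i],
      length = len, diameter = if (fu$is_ws[i]) 0.03 else 0.015,
      fu_id = fu$id[i]))
    fu$axis_id[i] <- nrow(axes)
  }
  out <- list(fu = fu, axes = axes, spacing = params$spacing,
              crown = c(radius = crown_radius, base = crown_base,
                        top = crown_top))
  class(out) <- c("orchard_tree", "list")
  out
}

#' @export
print.orchard_tree <- function(x, ...) {
  cat(sprintf("<orchard_tree> %d fruiting units (+%d water-sprout unit), %d fruits, %d axes\n",
              sum(!x$fu$is_ws), sum(x$fu$is_ws), sum(x$fu$n_fruits),
              nrow(x$axes)))
  cat(sprintf("  total leaf area %.2f m2, spacing %g x %g m\n",
              sum(x$fu$leaf_area), x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Write a tree description to a structured text file
#'
#' Two tab-separated blocks introduced by \code{#FU} and \code{#AXES} header
#' lines, mirroring the \code{fu} and \code{axes} tables of an
#' \code{orchard_tree}.
#' @param tree an \code{orchard_tree}.
#' @param path output file path.
#' @export
write_tree <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#SPACING", tree$spacing[1], tree$spacing[2], sep = "\t"),
             con)
  writeLines("#FU", con)
  utils::write.table(tree$fu, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("#AXES", con)
  utils::write.table(tree$axes, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a tree description written by \code{write_tree}
#' @param path file path.
#' @return an \code{orchard_tree}.
#' @export
read_tree <- function(path) {
  lines <- readLines(path)
  sp <- strsplit(lines[grep("^#SPACING", lines)[1]], "\t")[[1]]
  i_fu <- grep("^#FU$", lines)[1]
  i_ax <- grep("^#AXES$", lines)[1]
  fu <- utils::read.table(text = lines[(i_fu + 1):(i_ax - 1)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  axes <- utils::read.table(text = lines[(i_ax + 1):length(lines)],
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (any(fu$ax <= 0 | fu$ay <= 0 | fu$az <= 0))
    stop("non-positive ellipsoid semi-axes")
  out <- list(fu = fu, axes = axes,
              spacing = as.numeric(sp[2:3]),
              crown = c(radius = max(sqrt(fu$x^2 + fu$y^2)) + max(fu$ax),
                        base = min(fu$z) - max(fu$az),
                        top = max(fu$z) + max(fu$az)))
  class(out) <- c("orchard_tree", "list")
  out
}
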