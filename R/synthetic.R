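#' Parameters for the synthetic dental-arch generator
#'
#' The generator emulates the geometry a segmentation network must cope
#' with on intraoral scans: a smooth gingival band swept along a parabolic
#' dental arch carrying up to 14 convex tooth protrusions with distinct
#' normals. Lengths are in millimetres, sized like an adult arch.
#'
#' @param n_teeth number of teeth, 1..14 (default 14).
#' @param arch_width arch width at the open end (default 55).
#' @param arch_depth front-to-back arch depth (default 35).
#' @param tooth_radius length-2 range of tooth cap radii (default 2.4-3.1).
#' @param tooth_height length-2 range of tooth cap heights (default 4-6.5).
#' @param gingiva_band width of the gingival band across the arch
#'   (default 14).
#' @param gingiva_height height of the gingival ridge (default 2.5).
#' @param spacing_scale multiplier on inter-tooth arc spacing; 1 is a normal
#'   arch, ~0.9 brings adjacent caps into contact (crowding).
#' @param jitter_sd standard deviation of Gaussian vertex jitter (default
#'   0.05, i.e. scanner-noise scale).
#' @param target_faces face count after decimation (default 10000).
#' @param seed integer seed; fully determines the output.
#' @return An `arch_params` list.
#' @export
arch_params <- function(n_teeth = 14L, arch_width = 55, arch_depth = 35,
                        tooth_radius = c(2.4, 3.1),
                        tooth_height = c(4, 6.5),
                        gingiva_band = 14, gingiva_height = 2.5,
                        spacing_scale = 1, jitter_sd = 0.05,
                        target_faces = 10000L, seed = 1L) {
  n_teeth <- as.integer(n_teeth)
  if (n_teeth < 1L || n_teeth > 14L) stop("n_teeth must be in 1..14")
  lens <- c(arch_width, arch_depth, tooth_radius, tooth_height,
            gingiva_band, gingiva_height, spacing_scale)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  if (target_faces < 100L) stop("target_faces must be at least 100")
  structure(list(n_teeth = n_teeth, arch_width = arch_width,
                 arch_depth = arch_depth, tooth_radius = tooth_radius,
                 tooth_height = tooth_height, gingiva_band = gingiva_band,
                 gingiva_height = gingiva_height,
                 spacing_scale = spacing_scale, jitter_sd = jitter_sd,
                 target_faces = as.integer(target_faces),
                 seed = as.integer(seed)),
            class = "arch_params")
}

# parabolic centerline of the arch: u in [0,1] -> (x, y)
arch_centerline <- function(u, width, depth) {
  cbind(x = width * (u - 0.5), y = depth * (1 - (2 * u - 1)^2))
}

# tooth positions equally spaced in arc length (not in u)
arch_tooth_u <- function(n_teeth, width, depth, margin = 0.04) {
  ug <- seq(0, 1, length.out = 2001)
  cl <- arch_centerline(ug, width, depth)
  seg <- sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  lo <- margin * total; hi <- (1 - margin) * total
  st <- lo + (seq_len(n_teeth) - 0.5) / n_teeth * (hi - lo)
  stats::approx(s, ug, xout = st)$y
}

#' Generate a labeled synthetic dental arch
#'
#' Builds a parametric gingiva-plus-teeth surface (see [arch_params()]),
#' labels every face (0 = gingiva, 1..n_teeth = teeth, numbered
#' left-to-right), adds Gaussian vertex jitter and decimates to
#' `target_faces` by quadric edge collapse with nearest-centroid label
#' transfer. Deterministic given `params$seed`.
#'
#' @param params an [arch_params()] object.
#' @return A labeled [triangle_mesh()].
#' @export
generate_arch <- function(params = arch_params()) {
  p <- params
  with_seed(p$seed, {
    u_t <- arch_tooth_u(p$n_teeth, p$arch_width, p$arch_depth)
    r_t <- stats::runif(p$n_teeth, p$tooth_radius[1], p$tooth_radius[2])
    h_t <- stats::runif(p$n_teeth, p$tooth_height[1], p$tooth_height[2])
    centers <- arch_centerline(u_t, p$arch_width, p$arch_depth)
    # contract spacing toward the arch middle tooth for crowding
    if (p$spacing_scale != 1) {
      mid <- colMeans(centers)
      centers <- matrix(mid, p$n_teeth, 2, byrow = TRUE) +
        (centers - matrix(mid, p$n_teeth, 2, byrow = TRUE)) * p$spacing_scale
    }
    if (p$n_teeth > 1) {
      dd <- sqrt(rowSums((centers[-1, , drop = FALSE] -
                            centers[-p$n_teeth, , drop = FALSE])^2))
      lim <- 0.75 * (r_t[-1] + r_t[-p$n_teeth])
      if (any(dd < lim))
        stop("teeth overlap beyond the allowed threshold; ",
             "increase spacing or reduce tooth_radius")
    }

    # parametric grid sized so the raw mesh oversamples the target ~1.3x
    quads <- ceiling(0.65 * max(p$target_faces, 2000))
    nv_ <- max(12L, as.integer(round(sqrt(quads / 7))))
    nu_ <- max(24L, as.integer(ceiling(quads / nv_)))
    ug <- seq(0, 1, length.out = nu_ + 1L)
    vg <- seq(-1, 1, length.out = nv_ + 1L)
    cl <- arch_centerline(ug, p$arch_width, p$arch_depth)
    # unit normal of the centerline in the xy-plane
    tx <- rep(p$arch_width, length(ug))
    ty <- -4 * p$arch_depth * (2 * ug - 1)
    tl <- sqrt(tx^2 + ty^2)
    nx <- -ty / tl; ny <- tx / tl

    nu1 <- length(ug); nv1 <- length(vg)
    U <- rep(seq_len(nu1), times = nv1)
    Vv <- rep(vg, each = nu1)
    px <- cl[U, 1] + Vv * (p$gingiva_band / 2) * nx[U]
    py <- cl[U, 2] + Vv * (p$gingiva_band / 2) * ny[U]
    z <- p$gingiva_height * (1 - Vv^2)
    bump_best <- numeric(length(px))
    bump_who <- integer(length(px))
    for (t in seq_len(p$n_teeth)) {
      dh2 <- (px - centers[t, 1])^2 + (py - centers[t, 2])^2
      b <- h_t[t] * pmax(0, 1 - dh2 / r_t[t]^2)^1.5
      upd <- b > bump_best
      bump_best[upd] <- b[upd]
      bump_who[upd] <- t
    }
    z <- z + bump_best
    verts <- cbind(px, py, z)
    if (p$jitter_sd > 0)
      verts <- verts + matrix(stats::rnorm(length(verts), 0, p$jitter_sd),
                              ncol = 3)

    # two triangles per grid quad, wound so normals point up (+z outward)
    i <- rep(seq_len(nu1 - 1L), times = nv1 - 1L)
    j <- rep(seq_len(nv1 - 1L), each = nu1 - 1L)
    a <- (j - 1L) * nu1 + i
    b2 <- a + 1L
    c2 <- a + nu1
    d2 <- c2 + 1L
    faces <- rbind(cbind(a, b2, d2), cbind(a, d2, c2))

    mesh <- triangle_mesh(verts, faces, n_classes = p$n_teeth + 1L)
    cen <- face_centroids(mesh)
    lab <- integer(n_faces(mesh))
    best <- numeric(n_faces(mesh))
    for (t in seq_len(p$n_teeth)) {
      dh2 <- (cen[, 1] - centers[t, 1])^2 + (cen[, 2] - centers[t, 2])^2
      b <- h_t[t] * pmax(0, 1 - dh2 / r_t[t]^2)^1.5
      upd <- b > best
      best[upd] <- b[upd]
      lab[upd] <- t
    }
    lab[best < 0.08 * h_t[pmax(lab, 1L)]] <- 0L
    mesh <- attach_labels(mesh, lab, n_classes = p$n_teeth + 1L)
    mesh <- decimate(mesh, p$target_faces)
    attr(mesh, "arch_info") <- list(params = p, tooth_centers = centers,
                                    tooth_radius = r_t, tooth_height = h_t)
    mesh
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Draws `n_models` arches with per-model parameter perturbations (arch size
#' +-5%, tooth size ranges jittered) from seeded streams. Roughly 30% of the
#' models use the crowded preset (reduced inter-tooth spacing), mirroring a
#' normal/malformed case mix.
#'
#' @param n_models number of meshes to generate (>= 1).
#' @param base_params an [arch_params()] template.
#' @param seed integer master seed.
#' @param crowded_frac fraction of models drawn with crowded spacing
#'   (default 0.3).
#' @return list with `meshes` (list of labeled [triangle_mesh()]) and
#'   `manifest` (per-model parameters, seeds and preset).
#' @export
make_dataset <- function(n_models, base_params = arch_params(), seed = 0L,
                         crowded_frac = 0.3) {
  if (n_models < 1L) stop("n_models must be >= 1")
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_models),
    wjit = stats::runif(n_models, 0.95, 1.05),
    djit = stats::runif(n_models, 0.95, 1.05),
    crowded = stats::runif(n_models) < crowded_frac
  ))
  meshes <- vector("list", n_models)
  manifest <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    pm <- base_params
    pm$arch_width <- pm$arch_width * draws$wjit[m]
    pm$arch_depth <- pm$arch_depth * draws$djit[m]
    # tooth size follows jaw size so inter-tooth clearance stays anatomical
    sjit <- (draws$wjit[m] + draws$djit[m]) / 2
    pm$tooth_radius <- pm$tooth_radius * sjit
    pm$tooth_height <- pm$tooth_height * sjit
    pm$spacing_scale <- if (draws$crowded[m]) 0.9 * pm$spacing_scale
                        else pm$spacing_scale
    pm$seed <- draws$seeds[m]
    meshes[[m]] <- generate_arch(pm)
    manifest[[m]] <- list(model = m, preset = if (draws$crowded[m])
      "crowded" else "normal", params = unclass(pm))
  }
  list(meshes = meshes,
       manifest = list(seed = as.integer(seed), n_models = n_models,
                       crowded_frac = crowded_frac, models = manifest))
}

#' Icosphere test surface
#'
#' A unit icosahedron subdivided `subdiv` times with vertices projected onto
#' the unit sphere; 20 * 4^subdiv faces. A standard closed test surface for
#' decimation and geometry checks.
#'
#' @param subdiv number of 4-to-1 subdivisions (default 3, 1280 faces).
#' @return A [triangle_mesh()].
#' @export
icosphere <- function(subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    key <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- key[[k]]
      if (!is.null(id)) return(id)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      key[[k]] <- id
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    r <- 1L
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[r, ] <- c(a, ab, ca)
      nf[r + 1L, ] <- c(b, bc, ab)
      nf[r + 2L, ] <- c(c3, ca, bc)
      nf[r + 3L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- verts
    f <- nf
  }
  triangle_mesh(v, f)
}
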