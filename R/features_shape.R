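# Shape family: volume, mesh surface area, sphericity, compacity.

# Marching-tetrahedra lookup: each grid cell (2x2x2 voxel centres) is split
# into 6 tetrahedra around the main diagonal; for a binary field every
# iso-crossing sits at an edge midpoint, so the interface area contributed by
# a tetrahedron depends only on which of its 4 corners are inside. The
# 6 x 16 table of area constants (voxel units) is built once.
mt_table <- function() {
  if (!is.null(the_cache$mt)) return(the_cache$mt)
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))  # id = row
  corner_id <- function(p) 1L + p[1] + 2L * p[2] + 4L * p[3]
  ey <- diag(3)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  tets <- matrix(0L, 6L, 4L)
  tet_coords <- vector("list", 6L)
  for (t in 1:6) {
    p <- perms[[t]]
    vs <- rbind(c(0, 0, 0), ey[p[1], ], ey[p[1], ] + ey[p[2], ], c(1, 1, 1))
    tet_coords[[t]] <- vs
    tets[t, ] <- apply(vs, 1L, corner_id)
  }
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  areas <- matrix(0, 6L, 16L)
  for (t in 1:6) {
    vs <- tet_coords[[t]]
    for (code in 0:15) {
      inside <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
      k <- length(inside)
      if (k == 0L || k == 4L) next
      if (k == 2L) {
        a <- inside[1]; b <- inside[2]
        o <- setdiff(1:4, inside)
        mac <- (vs[a, ] + vs[o[1], ]) / 2; mad <- (vs[a, ] + vs[o[2], ]) / 2
        mbc <- (vs[b, ] + vs[o[1], ]) / 2
        areas[t, code + 1L] <- sqrt(sum(cross3(mad - mac, mbc - mac)^2))
      } else {
        lone <- if (k == 1L) inside else setdiff(1:4, inside)
        rest <- setdiff(1:4, lone)
        m <- t(vapply(rest, function(r) (vs[lone, ] + vs[r, ]) / 2,
                      numeric(3)))
        areas[t, code + 1L] <-
          sqrt(sum(cross3(m[2, ] - m[1, ], m[3, ] - m[1, ])^2)) / 2
      }
    }
  }
  the_cache$mt <- list(tets = tets, areas = areas)
  the_cache$mt
}

#' Mesh surface area of a mask
#'
#' Area (mm^2) of the marching-tetrahedra iso-surface of the binary mask
#' (iso-level midway between inside and outside, zero-padded). A
#' single-voxel mask is a documented special case returning its exposed cube
#' faces, `6 s^2`.
#'
#' @param mask a [voi_mask()].
#' @return surface area in mm^2.
#' @export
surface_area <- function(mask) {
  s <- mask$spacing[1]
  if (mask$voxel_count == 1L) return(6 * s^2)
  dims <- dim(mask$values)
  pad <- array(0L, dims + 2L)
  pad[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <-
    as.integer(mask$values)
  cd <- dims + 1L  # cells
  corner <- function(bx, by, bz)
    as.integer(pad[(1:cd[1]) + bx, (1:cd[2]) + by, (1:cd[3]) + bz])
  b <- list(corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(0L, 1L, 0L),
            corner(1L, 1L, 0L), corner(0L, 0L, 1L), corner(1L, 0L, 1L),
            corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  tbl <- mt_table()
  area <- 0
  for (t in 1:6) {
    ids <- tbl$tets[t, ]
    code <- b[[ids[1]]] + 2L * b[[ids[2]]] + 4L * b[[ids[3]]] +
      8L * b[[ids[4]]]
    area <- area + sum(tabulate(code + 1L, 16L) * tbl$areas[t, ])
  }
  area * s^2
}

#' Shape features
#'
#' Volume (ml), mesh surface area A (mm^2, see [surface_area()]),
#' sphericity `pi^(1/3) (6 V)^(2/3) / A` and compacity
#' `V / (sqrt(pi) A^(3/2))` with V in mm^3 (both dimensionless; conventions
#' recorded here).
#'
#' @param mask a nonempty [voi_mask()].
#' @return named numeric vector over the shape family.
#' @export
shape_features <- function(mask) {
  if (mask$voxel_count == 0L) stopf("mask is empty")
  v_mm3 <- mask$volume_ml * 1000
  a <- surface_area(mask)
  c(Volume = mask$volume_ml,
    Sphericity = pi^(1 / 3) * (6 * v_mm3)^(2 / 3) / a,
    Surface_Area = a,
    Compacity = v_mm3 / (sqrt(pi) * a^1.5))
}
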