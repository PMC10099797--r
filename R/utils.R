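# Internal helpers shared across modules.

# Evaluate f() with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards so library calls never perturb user simulations.
.with_seed <- function(seed, f) {
    if (is.null(seed)) return(f())
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    f()
}

# Label connected components of a 3-D binary mask (26-connectivity).
# Returns an integer array: 0 outside, component id inside. Ids are
# assigned in decreasing order of component size (1 = largest).
.label_components_3d <- function(mask) {
    d <- dim(mask)
    stopifnot(length(d) == 3L)
    lab <- array(0L, d)
    idx <- which(mask > 0)
    if (!length(idx)) return(lab)
    inside <- array(FALSE, d)
    inside[idx] <- TRUE
    # 26-neighbourhood linear offsets
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    comp <- 0L
    sizes <- integer()
    ar <- function(i) arrayInd(i, d)
    for (start in idx) {
        if (lab[start] != 0L) next
        comp <- comp + 1L
        queue <- start
        lab[start] <- comp
        n <- 0L
        while (length(queue)) {
            cur <- queue
            queue <- integer()
            n <- n + length(cur)
            ci <- arrayInd(cur, d)
            for (k in seq_len(nrow(offs))) {
                ni <- ci
                ni[, 1] <- ci[, 1] + offs[k, 1]
                ni[, 2] <- ci[, 2] + offs[k, 2]
                ni[, 3] <- ci[, 3] + offs[k, 3]
                ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] &
                      ni[, 2] >= 1 & ni[, 2] <= d[2] &
                      ni[, 3] >= 1 & ni[, 3] <= d[3]
                if (!any(ok)) next
                lin <- ni[ok, 1] + (ni[ok, 2] - 1) * d[1] +
                       (ni[ok, 3] - 1) * d[1] * d[2]
                lin <- lin[inside[lin] & lab[lin] == 0L]
                if (length(lin)) {
                    lab[lin] <- comp
                    queue <- c(queue, lin)
                }
            }
            queue <- unique(queue)
        }
        sizes[comp] <- n
    }
    # relabel by decreasing size
    o <- order(sizes, decreasing = TRUE)
    remap <- integer(comp)
    remap[o] <- seq_len(comp)
    nz <- lab != 0L
    lab[nz] <- remap[lab[nz]]
    lab
}

# Shift a 3-D array by integer offsets, padding with `fill`.
.shift3d <- function(x, dx, dy, dz, fill = 0) {
    d <- dim(x)
    out <- array(fill, d)
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    if (!length(sx) || !length(sy) || !length(sz)) return(out)
    out[sx, sy, sz] <- x[sx - dx, sy - dy, sz - dz]
    out
}

# Boxcar mean over a (2r+1)^3 neighbourhood restricted to `valid` voxels;
# returns list(mean =, count =). Voxels with count 0 get NA mean.
.box_mean_valid <- function(x, valid, r) {
    xs <- x
    xs[!valid] <- 0
    num <- array(0, dim(x))
    den <- array(0, dim(x))
    v <- valid * 1
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
        num <- num + .shift3d(xs, dx, dy, dz)
        den <- den + .shift3d(v, dx, dy, dz)
    }
    m <- num / den
    m[den == 0] <- NA_real_
    list(mean = m, count = den)
}

# Binary mask of an axis-aligned ellipsoid on a voxel grid (1-based
# centre/semi-axes in voxel units).
.ellipsoid_mask <- function(d, centre, semi) {
    ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
    gx <- ((ix - centre[1]) / semi[1])^2
    gy <- ((iy - centre[2]) / semi[2])^2
    gz <- ((iz - centre[3]) / semi[3])^2
    q <- outer(outer(gx, gy, "+"), gz, "+")
    array(q <= 1, d)
}
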