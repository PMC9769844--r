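# Shared fixtures built in code.

# Single-origin chromosome with the origin at the coordinate centre
# (linear LOESS then has its terminus at the plot edges) and C/tau set
# by `ctau`.
singleOriginSpec <- function(ctau = 1, L = 4.6e6, v = 30000, ...) {
    ChromosomeSpec(L, origins = L / 2, forkSpeed = v,
                   doublingTime = (L / 2) / v / ctau, ...)
}

# Three-origin chromosome mirroring a wild-type oriC plus two insertions
# at the lacZ and dadX/cvrA loci, with M9-glucose-like kinetics.
threeOriginSpec <- function(v = 30000, tau = 67) {
    ChromosomeSpec(4.6e6, origins = c(365000, 1240000, 3925000),
                   forkSpeed = v, doublingTime = tau)
}

table1Path <- function() {
    system.file("extdata", "table1_variants.tsv", package = "oriscope")
}

# Pointwise tricube weighted-least-squares oracle for the LOESS fit.
loessOracleAt <- function(x, y, i, span, degree) {
    n <- length(x)
    q <- ceiling(span * n)
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(q)]
    dmax <- max(d[idx])
    z <- (x[idx] - x[i]) / dmax
    w <- (1 - pmin(abs(z), 1)^3)^3
    fit <- stats::lm(y[idx] ~ stats::poly(z, degree = degree, raw = TRUE),
                     weights = w)
    unname(stats::coef(fit)[1L])
}
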