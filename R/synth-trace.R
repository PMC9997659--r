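#' Specification of a synthetic force-ramp scan
#'
#' Describes a magnetic-tweezers force-ramp experiment: the force rises
#' linearly as `F(t) = fStart + loadingRate * t` until `fMax`, each
#' tethered protein domain unfolds once at a stochastic force governed
#' by Bell-Evans kinetics `k(F) = k0 * exp(F * dx / kBT)`, and every
#' unfolding adds a fixed step to the bead height.
#'
#' @param loadingRate ramp rate r in pN/s (default 1, the standard
#'   protocol rate).
#' @param fStart,fMax force range in pN; `fMax` must not exceed 100 pN
#'   (instrument range).
#' @param sampleRate sampling rate in Hz (default 200).
#' @param noiseSd Gaussian height noise in nm (default 1, the typical
#'   extension resolution).
#' @param domains data.frame with columns `k0` (1/s), `dx` (nm) and
#'   `step` (nm step size); one row per unfoldable domain.  The default
#'   emulates a talin R1-R3-like construct with modal unfolding forces
#'   near 5, 15 and 25 pN and step sizes above 20 nm.
#' @param kBT thermal energy in pN nm (default 4.114, T = 298 K).
#' @param seed integer seed.
#' @return a validated `TraceSpec` list.
#' @export
traceSpec <- function(loadingRate = 1, fStart = 1, fMax = 35,
                      sampleRate = 200, noiseSd = 1,
                      domains = defaultDomains(), kBT = 4.114, seed = 1) {
    spec <- list(loadingRate = loadingRate, fStart = fStart, fMax = fMax,
                 sampleRate = sampleRate, noiseSd = noiseSd,
                 domains = domains, kBT = kBT, seed = as.integer(seed))
    validateTraceSpec(spec)
    class(spec) <- c("TraceSpec", "list")
    spec
}

validateTraceSpec <- function(spec) {
    with(spec, {
        if (!(fStart < fMax && fMax <= 100))
            stop("invalid spec: need fStart < fMax <= 100 pN")
        if (loadingRate < 0 || sampleRate <= 0 || noiseSd < 0 || kBT <= 0)
            stop("invalid spec: negative rate/noise or non-positive kBT")
        if (nrow(domains) &&
            (any(domains$k0 <= 0) || any(domains$dx <= 0) ||
             any(domains$step <= 0)))
            stop("invalid spec: k0, dx and step sizes must be positive")
    })
    invisible(TRUE)
}

#' Bell-Evans parameters reproducing a target modal ramp-unfolding force
#'
#' Under a linear ramp the modal unfolding force is, to leading order,
#' `F* = (kBT/dx) * log(r * dx / (k0 * kBT))`; inverting for `k0` lets a
#' domain be specified by the force at which its unfolding histogram
#' peaks.
#'
#' @param fStar target modal force (pN).
#' @param dx transition-state distance (nm).
#' @param rate loading rate (pN/s).
#' @param kBT thermal energy (pN nm).
#' @return intrinsic unfolding rate `k0` (1/s).
#' @export
bellEvansK0 <- function(fStar, dx, rate = 1, kBT = 4.114) {
    rate * dx / kBT * exp(-fStar * dx / kBT)
}

#' @rdname traceSpec
#' @export
defaultDomains <- function(kBT = 4.114, rate = 1) {
    data.frame(
        k0 = c(bellEvansK0(5, 4, rate, kBT),
               bellEvansK0(15, 2.5, rate, kBT),
               bellEvansK0(25, 2, rate, kBT)),
        dx = c(4, 2.5, 2),
        step = c(25, 22, 28))
}

## Invert the ramp survival function: with hazard k0*exp(F dx/kBT) and
## F = fStart + r t, S(F) = exp(-(k0 kBT)/(r dx) (e^{F dx/kBT} -
## e^{fStart dx/kBT})); given u ~ U(0,1) the unfolding force is the
## exact closed-form quantile.
sampleUnfoldingForce <- function(u, k0, dx, fStart, rate, kBT) {
    b <- dx / kBT
    (1 / b) * log(exp(b * fStart) + rate * b / k0 * (-log(u)))
}

#' Simulate a force-ramp bead-height trace
#'
#' Samples one unfolding force per domain from the exact Bell-Evans
#' ramp quantile function, builds the bead-height step function (each
#' unfolding adds the domain's step size), and adds Gaussian noise.
#' Domains whose sampled force exceeds `fMax` do not unfold within the
#' scan and are marked unresolved in the truth record.
#'
#' @param spec a [traceSpec()].
#' @return list with `trace` (a [ForceRampTrace-class]) and `truth`
#'   (data.frame: domain, force, time, step, resolved).
#' @examples
#' sim <- simulateTrace(traceSpec(seed = 7))
#' sim$truth
#' @export
simulateTrace <- function(spec) {
    validateTraceSpec(spec)
    tmax <- (spec$fMax - spec$fStart) / max(spec$loadingRate, 1e-12)
    tt <- seq(0, tmax, by = 1 / spec$sampleRate)
    nd <- nrow(spec$domains)
    out <- with_seed(spec$seed, {
        if (nd > 0) {
            u <- runif(nd)
            f_un <- sampleUnfoldingForce(u, spec$domains$k0,
                                         spec$domains$dx, spec$fStart,
                                         spec$loadingRate, spec$kBT)
        } else f_un <- numeric()
        noise <- if (spec$noiseSd > 0)
            rnorm(length(tt), sd = spec$noiseSd) else numeric(length(tt))
        list(f_un = f_un, noise = noise)
    })
    t_un <- (out$f_un - spec$fStart) / max(spec$loadingRate, 1e-12)
    resolved <- out$f_un <= spec$fMax
    height <- out$noise
    for (i in seq_len(nd)) {
        if (resolved[i])
            height <- height + spec$domains$step[i] * (tt >= t_un[i])
    }
    trace <- ForceRampTrace(
        time = tt, height = height,
        schedule = list(type = "linear", f_start = spec$fStart,
                        rate = spec$loadingRate, f_max = spec$fMax),
        sampleRate = spec$sampleRate)
    truth <- data.frame(domain = seq_len(nd), force = out$f_un,
                        time = t_un, step = spec$domains$step[seq_len(nd)],
                        resolved = resolved)
    list(trace = trace, truth = truth)
}

#' Write/read a force-ramp trace as TSV plus a JSON schedule sidecar
#'
#' The TSV has columns `time_s` and `height_nm`; the sidecar
#' `<path>.schedule.json` holds the force schedule and sample rate.
#'
#' @param trace a [ForceRampTrace-class].
#' @param path TSV path.
#' @return `path` (write) / a [ForceRampTrace-class] (read).
#' @export
writeTrace <- function(trace, path) {
    write.table(data.frame(time_s = trace@time, height_nm = trace@height),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_json(c(trace@schedule, list(sample_rate = trace@sampleRate)),
               paste0(path, ".schedule.json"), auto_unbox = TRUE,
               digits = NA)
    invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE)
    sc <- read_json(paste0(path, ".schedule.json"), simplifyVector = TRUE)
    rate <- sc$sample_rate
    sc$sample_rate <- NULL
    ForceRampTrace(df$time_s, df$height_nm, schedule = sc,
                   sampleRate = rate)
}
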