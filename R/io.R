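#' Build a run manifest
#'
#' A manifest captures everything needed to re-run an experiment:
#' model name, full parameter set, seeds, solver configuration and the
#' package version. Stored as JSON by [writeRun()].
#'
#' @param model model name
#' @param params named list of model parameters
#' @param seeds integer vector of RNG seeds used (if any)
#' @param config named list of solver settings
#' @param notes free-text annotation
#' @return a named list of class `"rbfcmeManifest"`
#' @export
runManifest <- function(model, params = list(), seeds = integer(),
                        config = list(), notes = "") {
  structure(list(model = model, params = params, seeds = seeds,
                 config = config, notes = notes,
                 package = as.character(utils::packageVersion("rbfCME")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "rbfcmeManifest")
}

#' Write a run bundle to disk
#'
#' Serialises a manifest, a per-step log table and any number of lattice
#' distributions into a directory of plain-text files: `manifest.json`,
#' `log.csv`, and one `dist_<name>.csv` per distribution (state
#' coordinates plus value; box bounds stored in the manifest). Everything
#' written by `writeRun` is read back losslessly by [readRun()].
#'
#' @param path target directory (created; its parent must exist)
#' @param manifest a [runManifest()] list
#' @param log data frame of per-step records (may be `NULL`)
#' @param distributions named list of [LatticeDistribution-class] objects
#' @param masks named list of [SupportMask-class] objects (e.g. accepted
#'   essential supports)
#' @return `path`, invisibly
#' @export
writeRun <- function(path, manifest, log = NULL, distributions = list(),
                     masks = list()) {
  parent <- dirname(path)
  if (!dir.exists(parent))
    stop("cannot write run: directory does not exist: ", parent)
  dir.create(path, showWarnings = FALSE)
  boxes <- lapply(c(distributions, masks), function(u)
    list(lower = u@box@lower, upper = u@box@upper, step = u@box@step))
  manifest$boxes <- boxes
  jsonlite::write_json(unclass(manifest), file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(log))
    utils::write.csv(log, file.path(path, "log.csv"), row.names = FALSE)
  for (nm in names(distributions)) {
    u <- distributions[[nm]]
    df <- as.data.frame(latticePoints(u@box))
    names(df) <- paste0("x", seq_len(u@box@d))
    df$value <- u@values
    utils::write.csv(df, file.path(path, sprintf("dist_%s.csv", nm)),
                     row.names = FALSE)
  }
  for (nm in names(masks)) {
    m <- masks[[nm]]
    df <- as.data.frame(latticePoints(m@box))
    names(df) <- paste0("x", seq_len(m@box@d))
    df$member <- as.integer(m@mask)
    utils::write.csv(df, file.path(path, sprintf("mask_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a run bundle written by [writeRun()]
#'
#' @param path run directory
#' @return list with `manifest`, `log` (or `NULL`), `distributions`
#'   (named list of [LatticeDistribution-class]) and `masks` (named list
#'   of [SupportMask-class])
#' @export
readRun <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a run directory (no manifest): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  logPath <- file.path(path, "log.csv")
  log <- if (file.exists(logPath)) utils::read.csv(logPath) else NULL
  files <- list.files(path, pattern = "^dist_.*\\.csv$")
  dists <- list()
  for (f in files) {
    nm <- sub("^dist_(.*)\\.csv$", "\\1", f)
    df <- utils::read.csv(file.path(path, f))
    b <- manifest$boxes[[nm]]
    box <- latticeBox(b$lower, b$upper, b$step)
    dists[[nm]] <- latticeDistribution(box, df$value)
  }
  masks <- list()
  for (f in list.files(path, pattern = "^mask_.*\\.csv$")) {
    nm <- sub("^mask_(.*)\\.csv$", "\\1", f)
    df <- utils::read.csv(file.path(path, f))
    b <- manifest$boxes[[nm]]
    box <- latticeBox(b$lower, b$upper, b$step)
    masks[[nm]] <- latticeMask(box, mask = df$member > 0)
  }
  list(manifest = manifest, log = log, distributions = dists, masks = masks)
}

#' Deterministic test fixtures
#'
#' * `"birth_death"`: 1-D chain with constant birth `lambda` and linear
#'   death `mu * x` on `[0, N]`; returns the network, box, and the
#'   truncated-Poisson(`lambda/mu`) stationary reference - the classical
#'   closed-form oracle.
#' * `"gaussian_ic"`: an on-lattice Gaussian
#'   \eqn{\exp(-\sum_k (x_k - centre_k)^2 / scale)} as an initial
#'   condition (function plus tabulated distribution).
#' * `"translating_mask"`: a disc-shaped support rigidly translated one
#'   grid cell per unit time, for level-set extrapolation tests.
#'
#' @param kind fixture family
#' @param params named list overriding the per-kind defaults
#'   (`birth_death`: `lambda = 5, mu = 1, N = 30`; `gaussian_ic`:
#'   `centre = c(133, 133), scale = 266, box`; `translating_mask`:
#'   `lower = c(0,0), upper = c(40, 20), centre = c(8, 10), radius = 4,
#'   speed = 1, steps = 3`)
#' @param seed RNG seed (kept in the output for provenance; the built-in
#'   kinds are deterministic)
#' @return a named list; see details above
#' @export
makeFixture <- function(kind = c("birth_death", "gaussian_ic",
                                 "translating_mask"),
                        params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  out <- switch(kind,
    birth_death = {
      lambda <- p("lambda", 5); mu <- p("mu", 1); N <- p("N", 30L)
      net <- new("ReactionNetwork", d = 1L, channels = list(
        channel(1L, function(s) rep(lambda, nrow(s)), "birth"),
        channel(-1L, function(s) mu * s[, 1], "death")),
        name = "birth_death", params = list(lambda = lambda, mu = mu),
        components = character())
      box <- latticeBox(0L, N)
      ref <- stats::dpois(0:N, lambda / mu)
      ref <- ref / sum(ref)
      list(network = net, box = box,
           reference = latticeDistribution(box, ref))
    },
    gaussian_ic = {
      centre <- p("centre", c(133, 133)); scale <- p("scale", 266)
      box <- p("box", latticeBox(rep(0L, length(centre)),
                                 rep(300L, length(centre))))
      fn <- function(s)
        exp(-rowSums(sweep(s, 2L, centre, "-")^2) / scale)
      list(fn = fn, box = box, u0 = latticeDistribution(box, fn),
           centre = centre, scale = scale)
    },
    translating_mask = {
      lower <- p("lower", c(0L, 0L)); upper <- p("upper", c(40L, 20L))
      centre <- p("centre", c(8, 10)); radius <- p("radius", 4)
      speed <- p("speed", 1); steps <- p("steps", 3L)
      box <- latticeBox(lower, upper)
      pts <- latticePoints(box)
      masks <- lapply(0:(steps - 1L), function(i) {
        c2 <- centre + c(speed * i, 0)
        new("SupportMask", box = box,
            mask = rowSums(sweep(pts, 2L, c2, "-")^2) <= radius^2)
      })
      list(masks = masks, box = box, times = 0:(steps - 1L),
           speed = speed)
    })
  out$seed <- as.integer(seed)
  out$kind <- kind
  out
}
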