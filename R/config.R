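#' Build a reaction network from a plain-text configuration file
#'
#' YAML (or JSON) schema:
#' \preformatted{
#' model: toggle2d | tristable3d | ocs | self_regulating_gene | custom
#' params: { name: number, ... }        # passed to the model builder
#' channels:                            # custom models only
#'   - shift: [1, 0]
#'     propensity: "c1 / (c2 + x2^2)"   # arithmetic over x1..xd and params
#' components: [on, off]                # optional discrete component labels
#' }
#' Propensity expressions are arithmetic-only (`+ - * / ^`, parentheses,
#' numbers, `x1..xd`, parameter names); anything else is rejected, so a
#' configuration file can never execute code.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`)
#' @return a [ReactionNetwork-class] identical to the corresponding
#'   programmatic builder output for built-in model names
#' @export
parseNetworkConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config error: missing 'model' key")
  params <- cfg$params
  if (!is.null(params)) {
    bad <- names(params)[!vapply(params, is.numeric, logical(1L))]
    if (length(bad))
      stop("config error: non-numeric parameter(s): ",
           paste(bad, collapse = ", "))
  }
  switch(as.character(cfg$model),
    toggle2d = do.call(toggleParams, params %||% list()) |> buildToggle2d(),
    tristable3d = do.call(tristableParams, params %||% list()) |>
      buildTristable3d(),
    ocs = do.call(ocsParams, params %||% list()) |> buildOcs(),
    self_regulating_gene = do.call(geneModelParams, params %||% list()) |>
      buildSelfRegulatingGene(),
    custom = buildCustomNetwork(cfg, path),
    stop("config error: unknown model name '", cfg$model, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

buildCustomNetwork <- function(cfg, path) {
  if (is.null(cfg$channels) || !length(cfg$channels))
    stop("config error: custom model without channels (", path, ")")
  params <- lapply(cfg$params %||% list(), as.numeric)
  if (any(unlist(params) < 0))
    stop("config error: negative rate constant in ", path)
  # normalise data-frame form (JSON simplification) to a list of records
  chans <- cfg$channels
  if (is.data.frame(chans))
    chans <- lapply(seq_len(nrow(chans)), function(i)
      list(shift = chans$shift[[i]], propensity = chans$propensity[[i]]))
  d <- length(chans[[1L]]$shift)
  built <- vector("list", length(chans))
  for (i in seq_along(chans)) {
    chn <- chans[[i]]
    if (length(chn$shift) != d)
      stop("config error: channel ", i, " shift has wrong length")
    expr <- tryCatch(str2lang(as.character(chn$propensity)),
                     error = function(e)
                       stop("config error: unparsable propensity in channel ",
                            i, ": ", conditionMessage(e)))
    checkArithmetic(expr, d, names(params), i)
    fn <- makePropensityFun(expr, d, params)
    built[[i]] <- channel(as.integer(chn$shift), fn,
                          sprintf("custom R%d", i))
  }
  new("ReactionNetwork", d = as.integer(d), channels = built,
      name = "custom", params = params,
      components = as.character(cfg$components %||% character()))
}

checkArithmetic <- function(e, d, paramNames, chanId) {
  ok <- c("+", "-", "*", "/", "^", "(")
  recurse <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% paramNames || grepl("^x[0-9]+$", nm)) {
        if (grepl("^x[0-9]+$", nm) &&
            as.integer(sub("^x", "", nm)) > d)
          stop("config error: channel ", chanId, " references ", nm,
               " but the model has only ", d, " species")
        return(invisible())
      }
      stop("config error: unknown symbol '", nm, "' in channel ", chanId)
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% ok)
        stop("config error: operator or function '", op,
             "' not allowed in propensity expressions (channel ", chanId,
             ")")
      for (a in as.list(e)[-1L]) recurse(a)
      return(invisible())
    }
    stop("config error: invalid propensity expression in channel ", chanId)
  }
  recurse(e)
}

makePropensityFun <- function(expr, d, params) {
  force(expr); force(d); force(params)
  function(s) {
    env <- new.env(parent = baseenv())
    for (nm in names(params)) assign(nm, params[[nm]], envir = env)
    for (k in seq_len(d)) assign(paste0("x", k), s[, k], envir = env)
    rep_len(as.numeric(eval(expr, env)), nrow(s))
  }
}
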