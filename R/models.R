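#' Toggle-switch parameter sets
#'
#' `toggleParams()` builds the 2-D bistable parameter object; its defaults
#' are the classical set \eqn{c_1=c_4=3\cdot 10^3}, \eqn{c_2=c_5=1.1\cdot
#' 10^4}, \eqn{c_3=c_6=10^{-3}}, \eqn{\beta=\gamma=2}.
#' `tristableParams()` builds the symmetric 3-D generalisation (defaults:
#' the same constants replicated over the three species).
#' `tristableParamsReduced()` is a reduced-copy-number variant of the
#' tristable switch whose three asymmetric modes sit near coordinate 27, so
#' that the full-grid solver remains tractable; see the package vignette for
#' the derivation (a naive proportional scaling of the Hill half-point
#' destroys the corner attractors, so the reduced set sharpens repression:
#' \eqn{c_1=c_4=c_7=4.4}, \eqn{c_2=c_5=c_8=16}, \eqn{c_3=c_6=c_9=10^{-2}}).
#'
#' @param c1,c2,c3,c4,c5,c6,c7,c8,c9 positive rate constants
#' @param beta,gamma,zeta Hill exponents (>= 1)
#' @return a [ToggleParams-class]
#' @export
toggleParams <- function(c1 = 3e3, c2 = 1.1e4, c3 = 1e-3,
                         c4 = 3e3, c5 = 1.1e4, c6 = 1e-3,
                         beta = 2, gamma = 2) {
  new("ToggleParams", rates = c(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                                c5 = c5, c6 = c6),
      exps = c(beta = beta, gamma = gamma), d = 2L)
}

#' @rdname toggleParams
#' @export
tristableParams <- function(c1 = 3e3, c2 = 1.1e4, c3 = 1e-3,
                            c4 = 3e3, c5 = 1.1e4, c6 = 1e-3,
                            c7 = 3e3, c8 = 1.1e4, c9 = 1e-3,
                            beta = 2, gamma = 2, zeta = 2) {
  new("ToggleParams", rates = c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
                                c6 = c6, c7 = c7, c8 = c8, c9 = c9),
      exps = c(beta = beta, gamma = gamma, zeta = zeta), d = 3L)
}

#' @rdname toggleParams
#' @export
tristableParamsReduced <- function() {
  tristableParams(c1 = 4.4, c2 = 16, c3 = 1e-2,
                  c4 = 4.4, c5 = 16, c6 = 1e-2,
                  c7 = 4.4, c8 = 16, c9 = 1e-2)
}

channel <- function(shift, propensity, name)
  new("ReactionChannel", shift = as.integer(shift), propensity = propensity,
      name = name)

#' Bistable genetic toggle switch (two mutually repressing genes)
#'
#' Four channels over states \eqn{(x,y)}: production of each species with a
#' Hill-repressed rate and first-order degradation,
#' \deqn{a_1 = c_1/(c_2 + y^\beta),\; a_2 = c_3 x,\;
#'       a_3 = c_4/(c_5 + x^\gamma),\; a_4 = c_6 y.}
#'
#' @param params a [ToggleParams-class] with `d = 2` (default
#'   [toggleParams()])
#' @return a [ReactionNetwork-class] with `d = 2`, channels ordered
#'   `R1..R4` with shifts (+1,0), (-1,0), (0,+1), (0,-1)
#' @examples
#' net <- buildToggle2d()
#' propensities(net, c(0, 0))  # a1 = 3000/11000, a2 = a4 = 0
#' @export
buildToggle2d <- function(params = toggleParams()) {
  stopifnot(is(params, "ToggleParams"))
  if (params@d != 2L) stop("buildToggle2d needs a 2-species parameter set")
  r <- params@rates; e <- params@exps
  chans <- list(
    channel(c(1L, 0L),  function(s) r[["c1"]] / (r[["c2"]] + s[, 2]^e[["beta"]]),  "R1: 0 -> A"),
    channel(c(-1L, 0L), function(s) r[["c3"]] * s[, 1],                            "R2: A -> 0"),
    channel(c(0L, 1L),  function(s) r[["c4"]] / (r[["c5"]] + s[, 1]^e[["gamma"]]), "R3: 0 -> B"),
    channel(c(0L, -1L), function(s) r[["c6"]] * s[, 2],                            "R4: B -> 0"))
  new("ReactionNetwork", d = 2L, channels = chans, name = "toggle2d",
      params = as.list(c(r, e)), components = character())
}

#' Tristable toggle switch (three mutually repressing species)
#'
#' Six channels over \eqn{(x,y,z)}; each species is produced at a rate
#' repressed by the SUM of the two competitors,
#' \deqn{a_1 = c_1/(c_2+(y+z)^\beta)}, etc., and degrades linearly. With
#' symmetric constants the network is equivariant under any permutation of
#' the three coordinates.
#'
#' @param params a [ToggleParams-class] with `d = 3`
#' @return a [ReactionNetwork-class] with `d = 3`, channels `R1..R6`
#' @export
buildTristable3d <- function(params = tristableParams()) {
  stopifnot(is(params, "ToggleParams"))
  if (params@d != 3L) stop("buildTristable3d needs a 3-species parameter set")
  r <- params@rates; e <- params@exps
  chans <- list(
    channel(c(1L, 0L, 0L),  function(s) r[["c1"]] / (r[["c2"]] + (s[, 2] + s[, 3])^e[["beta"]]),  "R1: 0 -> A"),
    channel(c(-1L, 0L, 0L), function(s) r[["c3"]] * s[, 1],                                       "R2: A -> 0"),
    channel(c(0L, 1L, 0L),  function(s) r[["c4"]] / (r[["c5"]] + (s[, 1] + s[, 3])^e[["gamma"]]), "R3: 0 -> B"),
    channel(c(0L, -1L, 0L), function(s) r[["c6"]] * s[, 2],                                       "R4: B -> 0"),
    channel(c(0L, 0L, 1L),  function(s) r[["c7"]] / (r[["c8"]] + (s[, 1] + s[, 2])^e[["zeta"]]),  "R5: 0 -> C"),
    channel(c(0L, 0L, -1L), function(s) r[["c9"]] * s[, 3],                                       "R6: C -> 0"))
  new("ReactionNetwork", d = 3L, channels = chans, name = "tristable3d",
      params = as.list(c(r, e)), components = character())
}

#' Osteochondral switch parameters
#'
#' Defaults are the published simulation set for the stem-cell
#' differentiation model: Hill coefficient 2; progenitor `ap=0.2, bp=0.5,
#' mp=10, cpp=0.1, cop=ccp=0.5, kp=0.1`; osteoblast/chondrocyte
#' `ao=ac=0.1, bo=bc=1, mo=mc=1, coo=ccc=0.1, coc=cco=0.1, ko=kc=0.1`.
#' `mp = 8` switches the system from the bistable to the tristable regime;
#' `zo > 0` adds a pro-osteogenic stimulus to the basal osteogenic activity.
#'
#' @param ao,ac,ap auto-activation strengths
#' @param bo,bc,bp basal activities
#' @param mo,mc,mp inflection points
#' @param coo,ccc,cpp self-inhibition strengths
#' @param coc,cco mutual O/C inhibition strengths
#' @param cop,ccp progenitor inhibition strengths on O and C
#' @param ko,kc,kp decay rates
#' @param beta Hill coefficient
#' @param zo pro-osteogenic stimulus (>= 0)
#' @return an [OCSParams-class]
#' @export
ocsParams <- function(ao = 0.1, ac = 0.1, ap = 0.2,
                      bo = 1, bc = 1, bp = 0.5,
                      mo = 1, mc = 1, mp = 10,
                      coo = 0.1, ccc = 0.1, cpp = 0.1,
                      coc = 0.1, cco = 0.1, cop = 0.5, ccp = 0.5,
                      ko = 0.1, kc = 0.1, kp = 0.1,
                      beta = 2, zo = 0) {
  new("OCSParams", ao = ao, ac = ac, ap = ap, bo = bo, bc = bc, bp = bp,
      mo = mo, mc = mc, mp = mp, coo = coo, ccc = ccc, cpp = cpp, coc = coc,
      cco = cco, cop = cop, ccp = ccp, ko = ko, kc = kc, kp = kp,
      beta = beta, zo = zo)
}

#' Osteochondral switch (OCS) stem-cell differentiation model
#'
#' Birth/death channel structure identical to [buildTristable3d()] with
#' asymmetric Hill propensities over \eqn{(x,y,z)} = (osteogenic,
#' chondrogenic, progenitor):
#' \deqn{a_1 = (a_o x^\beta + b_o + z_o) /
#'   (m_o + c_{oo}x^\beta + c_{oc}y^\beta + c_{op}z^\beta)}
#' and analogously for the chondrogenic (`a_3`) and progenitor (`a_5`)
#' factors (the progenitor is only self-inhibited); `a_2, a_4, a_6` are
#' linear decays. The stimulus `zo` enters only the osteogenic production.
#'
#' @param params an [OCSParams-class] (default [ocsParams()])
#' @return a [ReactionNetwork-class] with `d = 3`
#' @export
buildOcs <- function(params = ocsParams()) {
  stopifnot(is(params, "OCSParams"))
  p <- params; b <- p@beta
  chans <- list(
    channel(c(1L, 0L, 0L), function(s)
      (p@ao * s[, 1]^b + p@bo + p@zo) /
        (p@mo + p@coo * s[, 1]^b + p@coc * s[, 2]^b + p@cop * s[, 3]^b),
      "R1: 0 -> O"),
    channel(c(-1L, 0L, 0L), function(s) p@ko * s[, 1], "R2: O -> 0"),
    channel(c(0L, 1L, 0L), function(s)
      (p@ac * s[, 2]^b + p@bc) /
        (p@mc + p@ccc * s[, 2]^b + p@cco * s[, 1]^b + p@ccp * s[, 3]^b),
      "R3: 0 -> C"),
    channel(c(0L, -1L, 0L), function(s) p@kc * s[, 2], "R4: C -> 0"),
    channel(c(0L, 0L, 1L), function(s)
      (p@ap * s[, 3]^b + p@bp) / (p@mp + p@cpp * s[, 3]^b),
      "R5: 0 -> P"),
    channel(c(0L, 0L, -1L), function(s) p@kp * s[, 3], "R6: P -> 0"))
  prm <- list(ao = p@ao, ac = p@ac, ap = p@ap, bo = p@bo, bc = p@bc,
              bp = p@bp, mo = p@mo, mc = p@mc, mp = p@mp, coo = p@coo,
              ccc = p@ccc, cpp = p@cpp, coc = p@coc, cco = p@cco,
              cop = p@cop, ccp = p@ccp, ko = p@ko, kc = p@kc, kp = p@kp,
              beta = p@beta, zo = p@zo)
  new("ReactionNetwork", d = 3L, channels = chans, name = "ocs",
      params = prm, components = character())
}

#' Self-regulating gene parameters
#'
#' @param gOn,gOff protein production rates with free / repressed DNA
#' @param k protein degradation rate
#' @param f repressor release rate
#' @param h binding rate constant
#' @param bindingMode `"monomer"` (rate `h x`) or `"dimer"`
#'   (rate `h/2 x (x-1)`)
#' @return a [GeneModelParams-class]
#' @export
geneModelParams <- function(gOn = 20, gOff = 4, k = 1, f = 1, h = 0.1,
                            bindingMode = "monomer") {
  new("GeneModelParams", gOn = gOn, gOff = gOff, k = k, f = f, h = h,
      bindingMode = bindingMode)
}

#' Dimensionless characteristics of the gene model
#'
#' Adiabaticity \eqn{X^{ad} = (g_{on}+g_{off})/(2k)}, binding equilibrium
#' \eqn{X^{eq} = f/h} and relative unbinding speed \eqn{\omega = f/k}.
#' @param params a [GeneModelParams-class]
#' @return named numeric vector `Xad, Xeq, omega`
#' @export
geneModelScales <- function(params)
  c(Xad = (params@gOn + params@gOff) / (2 * params@k),
    Xeq = params@f / params@h, omega = params@f / params@k)

#' Self-regulating gene: a two-component master operator
#'
#' A single gene switches between a free (`on`) and a repressor-bound
#' (`off`) state while producing a protein that mediates its own repression.
#' The system is a pair of coupled one-dimensional master equations - not a
#' plain CME (the switching terms are multiplicative), but it is represented
#' here on a doubled lattice \eqn{(x, g)} with \eqn{g \in \{0=on, 1=off\}}
#' as a second axis, so the same operator machinery applies.
#'
#' Channels: production at `gOn` (free) or `gOff` (bound); degradation at
#' `k x`; binding `on -> off` at `h(x)` (monomer `h x`, dimer
#' `h/2 x (x-1)`); release `off -> on` at `f`. The bound state requires at
#' least one protein (`u_off(x) = 0` for `x < 1`): degradation of the last
#' free protein in the bound state moves \eqn{(1, off) \to (0, on)}, which
#' is the boundary balance of the governing equations, and the state
#' `(0, off)` is unreachable. The switching terms are implemented in the
#' probability-conserving orientation (every column of the assembled
#' operator sums to zero).
#'
#' @param params a [GeneModelParams-class]
#' @return a [ReactionNetwork-class] with `d = 2` and
#'   `components = c("on","off")`; use a box `[0,N] x [0,1]`
#' @export
buildSelfRegulatingGene <- function(params = geneModelParams()) {
  stopifnot(is(params, "GeneModelParams"))
  p <- params
  hx <- if (p@bindingMode == "monomer") {
    function(x) p@h * x
  } else {
    function(x) (p@h / 2) * x * (x - 1)
  }
  chans <- list(
    channel(c(1L, 0L), function(s)
      ifelse(s[, 2] == 0, p@gOn, p@gOff), "production"),
    channel(c(-1L, 0L), function(s)
      p@k * s[, 1] * (s[, 2] == 0 | s[, 1] >= 2), "degradation"),
    channel(c(0L, 1L), function(s)
      hx(s[, 1]) * (s[, 2] == 0 & s[, 1] >= 1), "binding: on -> off"),
    channel(c(0L, -1L), function(s)
      p@f * (s[, 2] == 1), "release: off -> on"),
    channel(c(-1L, -1L), function(s)
      p@k * (s[, 2] == 1 & s[, 1] == 1), "last-protein decay: (1,off) -> (0,on)"))
  new("ReactionNetwork", d = 2L, channels = chans,
      name = "self_regulating_gene",
      params = list(gOn = p@gOn, gOff = p@gOff, k = p@k, f = p@f, h = p@h,
                    bindingMode = p@bindingMode),
      components = c("on", "off"))
}

#' Evaluate all channel propensities at given states
#'
#' @param network a [ReactionNetwork-class]
#' @param states an `m x d` state matrix or a length-`d` vector
#' @return an `m x K` matrix, one column per channel
#' @export
propensities <- function(network, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  vapply(network@channels, function(ch) as.numeric(ch@propensity(states)),
         numeric(nrow(states)))
}

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork '%s': d=%d, %d channels%s\n", object@name,
              object@d, length(object@channels),
              if (length(object@components))
                sprintf(", components {%s}",
                        paste(object@components, collapse = ","))
              else ""))
  for (ch in object@channels)
    cat(sprintf("  [%s] shift (%s)\n", ch@name,
                paste(ch@shift, collapse = ",")))
})
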