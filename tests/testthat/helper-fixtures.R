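# Shared fixtures: all built in code, nothing on disk.

# A plan whose every pair is closed at 0 except the ones given in
# `prox`/`dist` (named by pair index, each a c(A, B)).
staticPlan <- function(prox = list(), dist = list(), mu = 100,
                       nCp = 2) {
  specs <- halcyonLayerSpecs()
  pp <- cbind(A = rep(0, 29), B = rep(0, 29))
  pd <- cbind(A = rep(0, 28), B = rep(0, 28))
  for (i in names(prox)) pp[as.integer(i), ] <- prox[[i]]
  for (i in names(dist)) pd[as.integer(i), ] <- dist[[i]]
  w <- seq(0, 1, length.out = nCp)
  cps <- lapply(seq_len(nCp), function(k)
    ControlPoint(k - 1L, w[k], 0,
                 list(proximal = pp, distal = pd)))
  DualLayerPlan(list(Beam(mu, cps, specs)),
                metadata = list(id = "static", target_class = "small"))
}

# Wide-open field: both layers fully retracted.
openFieldPlan <- function(mu = 100) {
  prox <- lapply(seq_len(29), function(i) c(-140, 140))
  names(prox) <- seq_len(29)
  dist <- lapply(seq_len(28), function(i) c(-140, 140))
  names(dist) <- seq_len(28)
  staticPlan(prox, dist, mu = mu)
}

# Tip model without transmissions/penumbra: pure geometric fluence.
bareModel <- function(penumbraSigma = 0, ...) {
  TipModel(transmission = c(proximal = 0, distal = 0),
           dualTransmission = 0, penumbraSigma = penumbraSigma, ...)
}

smallTestPlan <- function(seed = 11, nCp = 16)
  generateVmatPlan("small", nArcs = 1, nCpPerArc = nCp, seed = seed)
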