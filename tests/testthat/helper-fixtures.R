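## Shared in-code fixtures: small seeded cohorts and toy matrices.

smallCohort <- function(seed = 1, nResp = 6, nResis = 8, nGenes = 60,
                        nInf = 5, effect = 2, nPairs = 2) {
    generateCohort(syntheticConfig(nResponders = nResp,
                                   nResistant = nResis, nGenes = nGenes,
                                   nInformative = nInf,
                                   effectLog2fc = effect,
                                   nCorrPairs = nPairs, seed = seed))
}

## deterministic tiny RPKM matrix with named genes/samples
toyMatrix <- function(values, nGenes, nSamples) {
    m <- matrix(values, nGenes, nSamples)
    dimnames(m) <- list(sprintf("g%02d", seq_len(nGenes)),
                        sprintf("s%02d", seq_len(nSamples)))
    m
}

## independent dual-QP reference for the class-weighted linear SVM
## (kernlab interior-point solver; used as an oracle only)
qpReferenceSvm <- function(X, y, cResis, cResp) {
    yy <- ifelse(y == "responder", 1, -1)
    n <- length(yy)
    K <- X %*% t(X)
    H <- (yy %*% t(yy)) * K + diag(1e-10, n)
    Cvec <- ifelse(yy > 0, cResp, cResis)
    sol <- kernlab::ipop(c = matrix(-1, n), H = H, A = t(matrix(yy)),
                         b = 0, r = 0, l = matrix(0, n),
                         u = matrix(Cvec), sigf = 9)
    a <- kernlab::primal(sol)
    w <- drop(t(a * yy) %*% X)
    sv <- which(a > 1e-6 & a < Cvec - 1e-6)
    b <- mean(yy[sv] - X[sv, , drop = FALSE] %*% w)
    list(w = w, b = b)
}
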