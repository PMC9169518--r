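# Shared fixtures: the packaged catalog and the default anchor ladder are
# loaded once per test run.
.fixture_env <- new.env(parent = emptyenv())

fx_catalog <- function() {
  if (is.null(.fixture_env$catalog)) .fixture_env$catalog <- load_catalog()
  .fixture_env$catalog
}

fx_anchors <- function() {
  if (is.null(.fixture_env$anchors)) .fixture_env$anchors <- synth_anchor_series()
  .fixture_env$anchors
}

fx_templates <- function() {
  if (is.null(.fixture_env$templates))
    .fixture_env$templates <- default_templates(catalog = fx_catalog())
  .fixture_env$templates
}

candidate_ids <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                   "X", "XI", "XII", "XIII")

# a small profile_matrix with explicit values
fx_profiles <- function(values, species = "orange", subgroup = "none",
                        cultivar = NULL, prefix = "s") {
  values <- as.matrix(values)
  n <- nrow(values)
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  if (is.null(cultivar)) cultivar <- ids
  profile_matrix(sample_meta(ids, rep(species, n), rep(subgroup, n),
                             cultivar = cultivar, region = "r1",
                             harvest_year = 2020L),
                 values)
}

# minimal standalone NIPALS used as an independent oracle in a few tests
oracle_pls1_predict <- function(Xtr, ytr, Xte, ncomp) {
  mx <- colMeans(Xtr); sx <- apply(Xtr, 2, sd)
  Xs <- sweep(sweep(Xtr, 2, mx), 2, sx, "/")
  ys <- ytr - mean(ytr)
  W <- P <- NULL; q <- c()
  Xd <- Xs; yd <- ys
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd)); w <- w / sqrt(sum(w^2))
    t_ <- drop(Xd %*% w); tt <- sum(t_^2)
    p_ <- drop(crossprod(Xd, t_)) / tt
    q <- c(q, sum(yd * t_) / tt)
    Xd <- Xd - tcrossprod(t_, p_); yd <- yd - t_ * q[a]
    W <- cbind(W, w); P <- cbind(P, p_)
  }
  B <- W %*% solve(crossprod(P, W), q)
  Xts <- sweep(sweep(Xte, 2, mx), 2, sx, "/")
  mean(ytr) + drop(Xts %*% B)
}
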