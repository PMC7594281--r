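# Independent naive-enumeration oracles for the texture features: explicit
# per-pixel loops and scalar summations, no shared code with the package
# implementation. Used on small images where brute force is affordable.

.oracle_dirs <- list("0" = c(0, 1), "45" = c(-1, 1),
                     "90" = c(-1, 0), "135" = c(-1, -1))

oracle_glcm_prob <- function(labels, L, dir) {
  d <- .oracle_dirs[[dir]]
  nr <- nrow(labels); nc <- ncol(labels)
  P <- matrix(0, L, L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + d[1]; c2 <- c + d[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- labels[r, c]; b <- labels[r2, c2]
    if (a > 0 && b > 0) {
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  xlog2 <- function(x) if (x > 0) x * log2(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:L) { sx2 <- sx2 + (i - mux)^2 * px[i]
                   sy2 <- sy2 + (i - muy)^2 * py[i] }
  ac <- ctr <- dis <- ene <- ent <- hom <- idm <- idn <- idmn <- iv <- 0
  cp <- cs <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    ac <- ac + i * j * p
    ctr <- ctr + (i - j)^2 * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    ent <- ent - xlog2(p)
    hom <- hom + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idn <- idn + p / (1 + abs(i - j) / L)
    idmn <- idmn + p / (1 + (i - j)^2 / L^2)
    if (i != j) iv <- iv + p / (i - j)^2
  }
  corr <- if (sx2 > 0 && sy2 > 0) (ac - mux * muy) / sqrt(sx2 * sy2) else 0
  psum <- numeric(2 * L); pdif <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  sa <- 0; for (k in 2:(2 * L)) sa <- sa + k * psum[k]
  se <- 0; for (k in 2:(2 * L)) se <- se - xlog2(psum[k])
  sv <- 0; for (k in 2:(2 * L)) sv <- sv + (k - sa)^2 * psum[k]
  da <- 0; for (k in 0:(L - 1)) da <- da + k * pdif[k + 1]
  de <- 0; for (k in 0:(L - 1)) de <- de - xlog2(pdif[k + 1])
  dv <- 0; for (k in 0:(L - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  hx <- 0; for (i in 1:L) hx <- hx - xlog2(px[i])
  hy <- 0; for (j in 1:L) hy <- hy - xlog2(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    if (P[i, j] > 0 && px[i] * py[j] > 0)
      hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j])
    hxy2 <- hxy2 - xlog2(px[i] * py[j])
  }
  hmax <- max(hx, hy)
  imc1 <- if (hmax > 0) (ent - hxy1) / hmax else 0
  imc2 <- if (hmax > 0) sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))) else 0
  c(ac, ctr, corr, cp, cs, dis, ene, ent, hom, idm, max(P), sa, se, sv,
    de, dv, imc1, imc2, idn, idmn, iv)
}

oracle_glrlm_counts <- function(labels, L, dir) {
  d <- .oracle_dirs[[dir]]
  nr <- nrow(labels); nc <- ncol(labels)
  runs <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- labels[r, c]
    if (v <= 0) next
    rp <- r - d[1]; cp <- c - d[2]
    inside <- rp >= 1 && rp <= nr && cp >= 1 && cp <= nc
    if (inside && labels[rp, cp] == v) next  # not a run start
    len <- 1; rn <- r + d[1]; cn <- c + d[2]
    while (rn >= 1 && rn <= nr && cn >= 1 && cn <= nc &&
           labels[rn, cn] == v) {
      len <- len + 1; rn <- rn + d[1]; cn <- cn + d[2]
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  if (length(runs) == 0) return(NULL)
  runs <- do.call(rbind, runs)
  R <- matrix(0, L, max(runs[, 2]))
  for (k in seq_len(nrow(runs))) R[runs[k, 1], runs[k, 2]] <-
      R[runs[k, 1], runs[k, 2]] + 1
  R
}

oracle_rl_features <- function(R, np) {
  nr <- sum(R)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  mui <- muj <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    p <- R[i, j] / nr
    sre <- sre + p / j^2;          lre <- lre + p * j^2
    lgre <- lgre + p / i^2;        hgre <- hgre + p * i^2
    srlge <- srlge + p / (i * j)^2; srhge <- srhge + p * i^2 / j^2
    lrlge <- lrlge + p * j^2 / i^2; lrhge <- lrhge + p * (i * j)^2
    mui <- mui + i * p;            muj <- muj + j * p
  }
  glv <- rlv <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    p <- R[i, j] / nr
    glv <- glv + p * (i - mui)^2
    rlv <- rlv + p * (j - muj)^2
  }
  gln <- sum(rowSums(R)^2) / nr
  rln <- sum(colSums(R)^2) / nr
  c(sre, lre, gln, rln, nr / np, lgre, hgre, srlge, srhge, lrlge, lrhge,
    glv, rlv)
}

# 8-connected flood fill via an explicit stack
oracle_zones <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    v <- labels[r0, c0]
    if (v <= 0 || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- cur[1] + dr; c2 <- cur[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!seen[r2, c2] && labels[r2, c2] == v) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_counts <- function(labels, L) {
  z <- oracle_zones(labels)
  R <- matrix(0, L, max(z[, 2]))
  for (k in seq_len(nrow(z))) R[z[k, 1], z[k, 2]] <- R[z[k, 1], z[k, 2]] + 1
  R
}

oracle_ngtdm_parts <- function(labels, L) {
  nr <- nrow(labels); nc <- ncol(labels)
  n <- numeric(L); s <- numeric(L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- labels[r, c]
    if (v <= 0) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (labels[r2, c2] > 0) nb <- c(nb, labels[r2, c2])
    }
    if (length(nb) == 0) next
    n[v] <- n[v] + 1
    s[v] <- s[v] + abs(v - mean(nb))
  }
  list(n = n, s = s)
}

oracle_ngtdm_features <- function(n, s, eps = 1e-6) {
  N <- sum(n)
  p <- n / N
  occ <- which(p > 0)
  ng <- length(occ)
  coarse <- 1 / (eps + sum(p * s))
  if (ng < 2) return(c(coarse, 0, 0, 0, 0))
  ctr <- 0; den_b <- 0; cmplx <- 0; str_num <- 0
  for (i in occ) for (j in occ) {
    ctr <- ctr + p[i] * p[j] * (i - j)^2
    den_b <- den_b + abs(i * p[i] - j * p[j])
    cmplx <- cmplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
      (N * (p[i] + p[j]))
    str_num <- str_num + (p[i] + p[j]) * (i - j)^2
  }
  c(coarse,
    ctr / (ng * (ng - 1)) * sum(s) / N,
    sum(p * s) / (eps + den_b),
    cmplx,
    str_num / (eps + sum(s)))
}

# the full 52-feature vector of one quantized label image, by brute force
oracle_texture52 <- function(labels, L) {
  np <- sum(labels > 0)
  dir_avg <- function(per_dir) rowMeans(do.call(cbind, per_dir))
  glcm <- list(); glrlm <- list()
  for (d in names(.oracle_dirs)) {
    P <- oracle_glcm_prob(labels, L, d)
    if (!is.null(P)) glcm[[d]] <- oracle_glcm_features(P)
    R <- oracle_glrlm_counts(labels, L, d)
    if (!is.null(R)) glrlm[[d]] <- oracle_rl_features(R, np)
  }
  parts <- oracle_ngtdm_parts(labels, L)
  out <- c(dir_avg(glcm), dir_avg(glrlm),
           oracle_rl_features(oracle_glszm_counts(labels, L), np),
           oracle_ngtdm_features(parts$n, parts$s))
  names(out) <- texture_feature_names()
  out
}
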