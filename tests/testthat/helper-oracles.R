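# Shared fixtures and independent oracles used across the suite.

tiny_meta <- function(weight = 50, height = 160, sex = "male", dose = 250) {
  tibble::tibble(
    patient_id = "T001", sex = sex, age_years = 12,
    weight_kg = weight, height_cm = height,
    injected_dose_MBq = dose, uptake_time_min = 70
  )
}

# Uniform-value SUV image on a small grid.
uniform_suv <- function(value = 1, dim = c(16, 16, 16), spacing = c(4, 4, 4),
                        normalization = "bw") {
  petresponse:::new_suv_image(array(value, dim), spacing, normalization)
}

# Exhaustive voxel-centre membership test: triple loop, no shared code with
# the package's vectorised geometry.
brute_members <- function(dim, spacing, test_fun) {
  idx <- integer(0)
  for (k in seq_len(dim[3])) {
    for (j in seq_len(dim[2])) {
      for (i in seq_len(dim[1])) {
        p <- (c(i, j, k) - 0.5) * spacing
        if (test_fun(p)) {
          idx <- c(idx, i + (j - 1) * dim[1] + (k - 1) * dim[1] * dim[2])
        }
      }
    }
  }
  idx
}

in_sphere <- function(center, radius) {
  function(p) sum((p - center)^2) <= radius^2
}
in_box <- function(center, size) {
  function(p) all(abs(p - center) <= size / 2)
}
in_cylinder <- function(center, diameter, height) {
  function(p) {
    sum((p[1:2] - center[1:2])^2) <= (diameter / 2)^2 &&
      abs(p[3] - center[3]) <= height / 2
  }
}

# O(n^2) pairwise concordance AUC, ties counted one half.
brute_auc <- function(scores, labels, direction = "greater_positive") {
  s <- if (direction == "greater_positive") scores else -scores
  x <- s[labels == "relapse"]; y <- s[labels == "remission"]
  tot <- 0
  for (xi in x) for (yj in y) tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# Step-up BH adjustment straight from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- prev
  }
  adj
}

# Exhaustive cutoff scan: every midpoint plus the two outer candidates,
# maximum accuracy under an optional zero-false-negative constraint, ties
# by specificity then by fewest positive calls (recomputed independently).
brute_best_cutoff <- function(scores, labels, direction, npv100 = TRUE) {
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
  best <- NULL
  for (ct in cands) {
    pos <- if (direction == "greater_positive") scores > ct else scores < ct
    tp <- sum(pos & labels == "relapse"); fp <- sum(pos & labels == "remission")
    fn <- sum(!pos & labels == "relapse"); tn <- sum(!pos & labels == "remission")
    if (npv100 && fn > 0) next
    cand <- list(cutoff = ct, tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = (tp + tn) / length(scores),
                 spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 calls = tp + fp)
    if (is.null(best) ||
        cand$acc > best$acc + 1e-12 ||
        (abs(cand$acc - best$acc) < 1e-12 &&
         isTRUE(cand$spec > best$spec + 1e-12)) ||
        (abs(cand$acc - best$acc) < 1e-12 &&
         isTRUE(abs(cand$spec - best$spec) < 1e-12) &&
         cand$calls < best$calls)) {
      best <- cand
    }
  }
  best
}

# Random correlated two-marker instance for paired-AUC tests.
random_paired_instance <- function(n_pos = 15, n_neg = 25, shift = 1,
                                   rho_noise = 0.6) {
  n <- n_pos + n_neg
  latent <- c(rnorm(n_pos, shift), rnorm(n_neg))
  a <- latent + rnorm(n, 0, rho_noise)
  b <- latent + rnorm(n, 0, rho_noise)
  list(a = a, b = b,
       labels = rep(c("relapse", "remission"), c(n_pos, n_neg)))
}

# Stratified-bootstrap z-test of the paired AUC difference.
boot_auc_diff_p <- function(a, b, labels, B = 1e4) {
  pos <- which(labels == "relapse"); neg <- which(labels == "remission")
  auc_of <- function(s, p_idx, n_idx) {
    x <- s[p_idx]; y <- s[n_idx]
    r <- rank(c(x, y))
    (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
      (length(x) * length(y))
  }
  d_obs <- auc_of(a, pos, neg) - auc_of(b, pos, neg)
  d_star <- numeric(B)
  for (i in seq_len(B)) {
    p_s <- sample(pos, replace = TRUE)
    n_s <- sample(neg, replace = TRUE)
    d_star[i] <- auc_of(a, p_s, n_s) - auc_of(b, p_s, n_s)
  }
  se <- sd(d_star)
  if (se == 0) return(if (d_obs == 0) 1 else 0)
  2 * pnorm(-abs(d_obs / se))
}

# Mean of a normal truncated above at u.
trunc_norm_mean <- function(mu, sd, u) {
  a <- (u - mu) / sd
  mu - sd * dnorm(a) / pnorm(a)
}

# P(X > Y) for X, Y independent normals truncated above at u: the analytic
# AUC of a designed responder/non-responder separation.
trunc_norm_auc <- function(mu_x, sd_x, mu_y, sd_y, u = 100) {
  dx <- function(x) dnorm(x, mu_x, sd_x) / pnorm(u, mu_x, sd_x)
  py <- function(x) pmin(pnorm(pmin(x, u), mu_y, sd_y) / pnorm(u, mu_y, sd_y), 1)
  stats::integrate(function(x) dx(x) * py(x), mu_x - 10 * sd_x, u,
                   rel.tol = 1e-9)$value
}
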