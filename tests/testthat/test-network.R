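test_that("model layers are sized by the mask and config, deterministically", {
  fx <- tiny_cohort(p = 20, q = 5, seed = 2)
  cfg <- tiny_config()
  m <- init_model(cfg, fx$mask)
  expect_equal(dim(m$W$sp), c(length(fx$mask$gene_ids), nrow(fx$mask$matrix)))
  # masked positions carry no weight
  expect_true(all(m$W$sp[t(fx$mask$matrix) == 0] == 0))
  m2 <- init_model(cfg, fx$mask)
  expect_identical(m$W, m2$W)
  expect_error(init_model(tiny_config(n_embedding = 6, n_hidden2 = 6), fx$mask),
               "compress")
})

test_that("zero input with zero biases propagates to zero everywhere", {
  fx <- tiny_cohort(p = 12, q = 3, seed = 4)
  m <- init_model(tiny_config(), fx$mask)
  fw <- forward(m, matrix(0, 5, length(fx$mask$gene_ids)))
  expect_true(all(fw$embedding == 0))
  expect_true(all(fw$reconstruction == 0))
  expect_true(all(fw$risk == 0))
})

test_that("masked sparse weights are inert in outputs and gradients", {
  fx <- tiny_cohort(p = 12, q = 3, seed = 4)
  m <- init_model(tiny_config(seed = 9), fx$mask)
  X <- matrix(rnorm(6 * length(fx$mask$gene_ids)), 6)
  base <- forward(m, X)
  # blast a masked weight: outputs must not move
  off <- which(t(fx$mask$matrix) == 0)[1]
  m_perturbed <- m
  m_perturbed$W$sp[off] <- 1e9
  pert <- forward(m_perturbed, X)
  expect_identical(base$risk, pert$risk)
  expect_identical(base$reconstruction, pert$reconstruction)
  # gradients at masked positions are identically zero
  sv <- fx$cohort$survival[1:6, ]
  ev <- sv$event; ev[1] <- 1
  gr <- pathsurvnet:::model_gradients(m, X, sv$time, ev, gamma = 1, beta = 0)
  expect_true(all(gr$grads$W_sp[t(fx$mask$matrix) == 0] == 0))
})

test_that("forward is deterministic without dropout and row-equivariant", {
  fx <- tiny_cohort(p = 12, q = 3, seed = 5)
  m <- init_model(tiny_config(seed = 1), fx$mask)
  X <- matrix(rnorm(8 * length(fx$mask$gene_ids)), 8)
  f1 <- forward(m, X); f2 <- forward(m, X)
  expect_identical(f1$risk, f2$risk)
  perm <- sample(8)
  expect_equal(forward(m, X[perm, ])$risk, f1$risk[perm])
  # identical patients get identical scores
  Xdup <- X[c(1, 1, 2), ]
  rdup <- forward(m, Xdup)$risk
  expect_identical(rdup[1], rdup[2])
  expect_error(forward(m, X[, -1]), "expects")
})

test_that("analytic multitask gradients match finite differences", {
  fx <- tiny_cohort(n = 12, p = 8, q = 3, seed = 5)
  cfg <- tiny_config(n_hidden1 = 6, n_hidden2 = 5, n_embedding = 3,
                     weight_decay = 1e-3, seed = 2)
  model <- init_model(cfg, fx$mask)
  # move biases off the ReLU kinks that zero-init leaves at exactly 0
  set.seed(31)
  for (nm in pathsurvnet:::layer_names) {
    model$b[[nm]] <- rnorm(length(model$b[[nm]]), sd = 0.3)
  }
  X <- scale(fx$cohort$expression[1:12, fx$mask$gene_ids])
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  sv <- fx$cohort$survival[1:12, ]
  sv$event[1] <- 1
  Z0 <- forward(model, X)$embedding
  centers <- Z0[c(1, 5, 9), ] + matrix(rnorm(9, sd = 0.1), 3)
  s0 <- target_distribution(soft_assignment(Z0, centers))
  mask_t <- t(fx$mask$matrix)

  loss_of <- function(m) {
    fw <- forward(m, X)
    reg <- m$config$weight_decay * sum(vapply(pathsurvnet:::layer_names,
      function(nm) {
        w <- m$W[[nm]]
        if (nm == "sp") w <- w * mask_t
        sum(w^2) + sum(m$b[[nm]]^2)
      }, numeric(1)))
    reconstruction_loss(X, fw$reconstruction) +
      10 * clustering_loss(s0, soft_assignment(fw$embedding, centers)) +
      cox_loss(fw$risk, sv$time, sv$event) + reg
  }
  gr <- pathsurvnet:::model_gradients(model, X, sv$time, sv$event,
                                      gamma = 1, beta = 10,
                                      s_target = s0, centers = centers)
  set.seed(17)
  for (nm in pathsurvnet:::layer_names) {
    for (kind in c("W", "b")) {
      P <- if (kind == "W") model$W[[nm]] else model$b[[nm]]
      G <- gr$grads[[paste0(kind, "_", nm)]]
      for (ii in sample(length(P), min(4, length(P)))) {
        if (kind == "W" && nm == "sp" && mask_t[ii] == 0) next
        mp <- model; mm <- model
        if (kind == "W") {
          mp$W[[nm]][ii] <- mp$W[[nm]][ii] + 1e-6
          mm$W[[nm]][ii] <- mm$W[[nm]][ii] - 1e-6
        } else {
          mp$b[[nm]][ii] <- mp$b[[nm]][ii] + 1e-6
          mm$b[[nm]][ii] <- mm$b[[nm]][ii] - 1e-6
        }
        fd <- (loss_of(mp) - loss_of(mm)) / 2e-6
        expect_equal(G[ii], fd, tolerance = 1e-4,
                     label = paste("grad", kind, nm, ii))
      }
    }
  }
})

test_that("model checkpoints round-trip through save/load", {
  fx <- tiny_cohort(p = 12, q = 3, seed = 6)
  m <- init_model(tiny_config(), fx$mask)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  X <- matrix(rnorm(4 * length(fx$mask$gene_ids)), 4)
  expect_identical(forward(m, X)$risk, forward(m2, X)$risk)
})
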