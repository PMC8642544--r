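# Shared trained networks for the end-to-end tests.  Built lazily, once
# per session, at the study configuration for the teacher (64 units,
# 20 epochs x 500 samples) and at the reduced spiking size used by the
# fast suite (N = 160, fixed k = 75, eta = 1e-5, 2000 distillation
# samples — the largest training budget that keeps a full suite run
# inside a package-check session; the no-fast-feedback twin is trained
# identically with Omega_f = 0).

.stack_cache <- new.env(parent = emptyenv())

xor_stack <- function() {
  if (!is.null(.stack_cache$stack)) return(.stack_cache$stack)
  sampler <- xor_task_sampler()
  seed <- 1

  set.seed(derive_seed(seed, "teacher-init"))
  teacher <- rate_network(n_units = 64)
  set.seed(derive_seed(seed, "teacher-data"))
  fit <- train_rnn(sampler, teacher, epochs = 20, samples_per_epoch = 500)
  teacher <- fit$params

  n_distill <- 2000
  set.seed(derive_seed(seed, "ads-init"))
  net <- ads_network(teacher, n_neurons = 160)
  set.seed(derive_seed(seed, "ads-data"))
  dist <- train_ads(teacher, net, sampler,
                    feedback_schedule(75, n_distill, eta = 1e-5))

  set.seed(derive_seed(seed, "ads-init"))
  net0 <- ads_network(teacher, n_neurons = 160)
  net0$Omega_f <- net0$Omega_f * 0
  set.seed(derive_seed(seed, "ads-data"))
  dist0 <- train_ads(teacher, net0, sampler,
                     feedback_schedule(75, n_distill, eta = 1e-5))

  .stack_cache$stack <- list(
    teacher = teacher, teacher_loss = fit$loss_trace,
    net = dist$net, record = dist$record,
    net_nofast = dist0$net, sampler = sampler)
  .stack_cache$stack
}
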