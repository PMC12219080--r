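test_that("convolution arithmetic reproduces the printed layer sizes", {
  expect_equal(conv_output_size(150, 7), 144L)
  expect_equal(conv_output_size(144, 4, 0, 2), 71L)
  expect_equal(conv_output_size(65, 4, 0, 2), 31L)
  expect_equal(conv_output_size(25, 4, 0, 2), 11L)
  expect_equal(conv_output_size(11, 5), 7L)
  expect_equal(conv_output_size(7, 4, 0, 2), 2L)
  expect_error(conv_output_size(3, 7), "smaller")
  expect_error(conv_output_size(10, 3, 0, 0), "stride")
})

test_that("channel scaling shrinks widths but never spatial arithmetic", {
  full <- introspect_shapes(bilstm_cnn_spec(channel_scale = 1))
  eighth <- introspect_shapes(bilstm_cnn_spec(channel_scale = 0.125))
  sp_f <- full$height[grepl("^(conv|maxpool)", full$type)]
  sp_e <- eighth$height[grepl("^(conv|maxpool)", eighth$type)]
  expect_equal(sp_f, sp_e)  # spatial arithmetic untouched by channel scaling
  conv_f <- full$channels[grepl("^conv", full$type)]
  conv_e <- eighth$channels[grepl("^conv", eighth$type)]
  expect_equal(conv_e, pmax(1L, as.integer(round(conv_f * 0.125))))
  expect_error(bilstm_cnn_spec(bilstm_hidden_total = 127), "even")
})

test_that("a compiled dry forward pass agrees with the shape arithmetic", {
  spec <- bilstm_cnn_spec(channel_scale = 0.125, fusion_dim = 49)
  trace <- mammotex:::cpp_forward_trace(mammotex:::spec_for_engine(spec), 1)
  sh <- introspect_shapes(spec)
  conv_rows <- sh[grepl("^(conv|maxpool)", sh$type), ]
  trace_dims <- do.call(rbind, trace[grepl("^(conv|pool)", names(trace))])
  expect_equal(unname(trace_dims[, 1]), conv_rows$height)
  expect_equal(unname(trace_dims[, 3]), conv_rows$channels)
  expect_equal(trace$reshape[1], sh$height[sh$type == "reshape"])
  expect_equal(trace$bilstm[1], 128L)
  expect_equal(trace$concat[1], 128L + 49L)  # fusion concatenation width
  expect_equal(trace$softmax[1], 2L)
})

tiny_spec <- function(fusion = 3) {
  bilstm_cnn_spec(input_size = 16, channel_scale = 1, fusion_dim = fusion,
                  bilstm_hidden_total = 8, dense_units = 10,
                  dropout_conv = 0, dropout_lstm = 0,
                  conv_kernels = c(3, 3), conv_channels = c(2, 3),
                  conv_pools = c(FALSE, TRUE), conv_dropout = c(0, 0),
                  resample_after1 = 12, pool_kernel = 2, pool_stride = 2)
}

test_that("backpropagated gradients match finite differences", {
  spec <- tiny_spec()
  es <- mammotex:::spec_for_engine(spec)
  P <- mammotex:::cpp_init_params(es, 3)
  set.seed(42)
  img <- matrix(runif(256), 16, 16)
  feat <- rnorm(3)
  g <- mammotex:::cpp_loss_grad(es, P, img, feat, 1L)
  errs <- c()
  for (k in seq_along(P)) {
    ord <- order(abs(g$grads[[k]]), decreasing = TRUE)
    for (t in ord[seq_len(min(3, length(ord)))]) {
      ana <- g$grads[[k]][t]
      if (abs(ana) < 1e-3) next  # below single-precision resolution
      h <- 1e-2
      Pp <- P; Pp[[k]][t] <- Pp[[k]][t] + h
      Pm <- P; Pm[[k]][t] <- Pm[[k]][t] - h
      num <- (mammotex:::cpp_loss_grad(es, Pp, img, feat, 1L)$loss -
              mammotex:::cpp_loss_grad(es, Pm, img, feat, 1L)$loss) / (2 * h)
      errs <- c(errs, abs(num - ana) / max(abs(num), abs(ana)))
    }
  }
  # single-precision forward passes and occasional ReLU-kink crossings limit
  # individual agreement; a wrong gradient would be off by orders, not percent
  expect_gte(length(errs), 10)
  expect_lt(stats::median(errs), 0.02)
  expect_lt(max(errs), 0.20)
})

test_that("training is deterministic and memorises a separable toy set", {
  gen <- generate_dataset(phantom_params(), n_per_class = 10, seed = 0)
  ft <- feature_table(gen$dataset, test_pipeline_cfg())
  x <- as.matrix(ft[, hybrid_feature_names()])
  z <- apply_feature_scaler(fit_feature_scaler(x), x)
  spec <- bilstm_cnn_spec(channel_scale = 0.125, fusion_dim = 49)
  cfg <- train_config(learning_rate = 0.003, batch_size = 4, epochs = 5,
                      seed = 0)
  m1 <- train_model(build_model(spec), gen$dataset, z, cfg = cfg)
  p1 <- predict(m1, gen$dataset, z)
  expect_gte(mean(p1$label == gen$dataset$labels), 0.9)

  m2 <- train_model(build_model(spec), gen$dataset, z, cfg = cfg)
  p2 <- predict(m2, gen$dataset, z)
  expect_identical(m1$params, m2$params)
  expect_identical(p1, p2)
  expect_true(all(is.finite(m1$history$loss)))
})

test_that("prediction honours the softmax contract", {
  gen <- generate_dataset(phantom_params(size = c(224, 224)), 2, seed = 4)
  spec <- bilstm_cnn_spec(channel_scale = 0.125, fusion_dim = 0)
  m <- train_model(build_model(spec), gen$dataset,
                   cfg = train_config(epochs = 1, batch_size = 2, seed = 1))
  pr <- predict(m, gen$dataset$images[c(1, 1, 2)])
  expect_true(all(abs(pr$p_normal + pr$p_abnormal - 1) < 1e-6))
  expect_true(all(pr$p_normal >= 0 & pr$p_normal <= 1))
  expect_identical(pr[1, ], pr[2, ])  # duplicated input, identical output
})

test_that("degenerate training inputs are rejected", {
  gen <- generate_dataset(phantom_params(size = c(224, 224)), 2, seed = 4)
  one_class <- mammo_dataset(gen$dataset$images[c(1, 3)],
                             c("normal", "normal"))
  spec <- bilstm_cnn_spec(channel_scale = 0.125, fusion_dim = 0)
  expect_error(train_model(build_model(spec), one_class), "single class")
  expect_error(predict(build_model(spec), gen$dataset), "untrained")
  specf <- bilstm_cnn_spec(channel_scale = 0.125, fusion_dim = 49)
  expect_error(train_model(build_model(specf), gen$dataset,
                           features = matrix(0, 4, 3)), "fusion_dim")
})
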