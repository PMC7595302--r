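# Random fixtures shared across the suite. All draws go through local seeds
# so individual tests stay order-independent.

random_spec <- function(family, d = 5) {
  switch(family,
    linear = kernel_spec("linear"),
    poly   = kernel_spec("poly", gamma = runif(1, 0.3, 1.5), c0 = runif(1),
                         degree = sample(2:4, 1)),
    rbf    = kernel_spec("rbf", gamma = runif(1, 0.2, 2)),
    tanh   = kernel_spec("tanh", gamma = runif(1, 0.2, 1), c0 = runif(1, -0.5, 0.5)),
    ard    = kernel_spec("ard", nu = runif(1, 0.5, 2),
                         lengthscales = runif(d, 0.5, 2)))
}

random_expansion <- function(n = 10, d = 3, family = "rbf") {
  kernel_expansion(random_spec(family, d),
                   matrix(runif(n * d, -2, 2), n, d),
                   rnorm(n), bias = rnorm(1))
}

all_families <- c("linear", "poly", "rbf", "tanh", "ard")
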