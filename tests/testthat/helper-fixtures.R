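# shared fixture builders; everything is generated in code at test time

make_toy_clusters <- function() {
  cluster_dataset(data.frame(
    cluster_id = c("a", "b", "c"),
    x = c(0, 1, 2), y = c(0, 1, 0),
    n = c(10, 5, 4),
    y1 = c(8, 0, 4), y2 = c(6, 0, 4), y3 = c(3, 0, 4),
    cov1 = c(0.1, -0.2, 0.3)))
}

# random valid cluster dataset with monotone counts
random_clusters <- function(m, seed) {
  set.seed(seed)
  n <- sample(2:20, m, replace = TRUE)
  p1 <- runif(m); r21 <- runif(m); r32 <- runif(m)
  y1 <- round(n * p1)
  y2 <- round(y1 * r21)
  y3 <- round(y2 * r32)
  cluster_dataset(data.frame(
    cluster_id = sprintf("c%03d", seq_len(m)),
    x = runif(m, 0, 10), y = runif(m, 0, 10),
    n = n, y1 = y1, y2 = y2, y3 = y3,
    cov1 = rnorm(m)))
}

# two-rectangle admin geometry covering [0,2]x[0,1]
make_two_rect_units <- function() {
  rect <- function(x0, x1) rbind(c(x0, 0), c(x1, 0), c(x1, 1), c(x0, 1), c(x0, 0))
  list(list(unit_id = "L", level = "district", rings = list(rect(0, 1)),
            member_cells = character(0)),
       list(unit_id = "R", level = "district", rings = list(rect(1, 2)),
            member_cells = character(0)))
}

tiny_settings <- function(seed) {
  fit_settings(n_draws = 60, n_burn = 150, thin = 1, seed = seed,
               store_latent = FALSE)
}
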