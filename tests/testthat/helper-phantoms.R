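# Memoized phantom fixtures shared across test files; everything is
# generated in code, deterministically, on first use.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

phantom64 <- function(seed = 7L) {
  fixture(paste0("ph64_", seed), function()
    generate_phantom(phantom_config(shape = c(64L, 64L, 64L), seed = seed)))
}

phantom96 <- function(seed = 7L) {
  fixture(paste0("ph96_", seed), function()
    generate_phantom(phantom_config(seed = seed)))
}

# a tiny network configuration suitable for second-scale training runs
tiny_net_config <- function(dropout_conv = 0.05, dropout_fc = 0.1) {
  net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L), kernel_edge = 3L,
             fc_sizes = c(16L, 8L), dropout_conv = dropout_conv,
             dropout_fc = dropout_fc)
}

# distribution spec holding the binary classes at 1:1 given actual
# per-sub-label availability (phantoms rarely populate root-sediment /
# root-else, so the default n : n/2 request would leave root under-drawn)
availability_balanced_spec <- function(tabs, radii, n, seed) {
  spec <- distribution_spec(n, radii = radii, seed = seed)
  for (k in seq_along(radii)) {
    cnt <- tabs[[k]]$counts
    root_total <- sum(pmin(n, cnt[startsWith(names(cnt), "root-")]))
    nr <- names(cnt)[!startsWith(names(cnt), "root-") & cnt > 0L]
    per <- ceiling(root_total / length(nr))
    for (lab in names(cnt)) {
      i <- spec$sublabel == lab & spec$r == radii[k]
      spec$count[i] <- if (startsWith(lab, "root-")) min(n, cnt[[lab]])
                       else if (lab %in% nr) min(per, cnt[[lab]]) else 0L
    }
  }
  spec
}

# availability-balanced spec that additionally doubles the weight of the
# boundary hard negatives (sediment-root, else-root): the non-root half of
# the draw is split proportionally to these weights instead of uniformly
hard_balanced_spec <- function(tabs, radii, n, seed) {
  spec <- distribution_spec(n, radii = radii, seed = seed)
  for (k in seq_along(radii)) {
    cnt <- tabs[[k]]$counts
    root_total <- sum(pmin(n, cnt[startsWith(names(cnt), "root-")]))
    nr <- names(cnt)[!startsWith(names(cnt), "root-") & cnt > 0L]
    hard <- intersect(nr, c("sediment-root", "else-root"))
    w <- ifelse(nr %in% hard, 2, 1); w <- w / sum(w)
    for (lab in names(cnt)) {
      i <- spec$sublabel == lab & spec$r == radii[k]
      spec$count[i] <- if (startsWith(lab, "root-")) min(n, cnt[[lab]])
                       else if (lab %in% nr)
                         min(as.integer(ceiling(root_total * w[match(lab, nr)])),
                             cnt[[lab]])
                       else 0L
    }
  }
  spec
}
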