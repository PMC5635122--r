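# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

smoke_dataset <- function() cached_fixture("smoke", function() make_fixture("smoke"))

grid_population <- function() cached_fixture("grid", function() make_fixture("grid"))

# tiny bid table used by the delta_v / popularity unit tests
toy_bids <- function() {
  bid_profiles(
    participant = rep(c("p1", "p2", "p3", "p4"), each = 2),
    item = rep(c("apple", "crisps"), 4),
    bid_gbp = c(2.10, 0.60,   # p1 prefers apple
                1.00, 0.50,   # p2 prefers apple
                0.40, 1.80,   # p3 prefers crisps
                1.20, 1.20))  # p4 tied
}

toy_pair <- function() item_pairs("pr1", "apple", "crisps")
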