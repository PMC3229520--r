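test_that("rooted topology counts follow the double factorial", {
  expect_length(enumerate_rooted_topologies(c("a", "b", "c")), 3L)
  expect_length(enumerate_rooted_topologies(letters[1:4]), 15L)
  expect_length(enumerate_rooted_topologies(letters[1:5]), 105L)
  expect_error(enumerate_rooted_topologies("a"), "at least 2")
  expect_error(enumerate_rooted_topologies(c("a", "a")), "duplicate")
})

test_that("enumerated topologies are distinct and deterministically ordered", {
  t1 <- enumerate_rooted_topologies(letters[1:4])
  t2 <- enumerate_rooted_topologies(rev(letters[1:4]))
  expect_identical(names(t1), names(t2))        # label order irrelevant
  expect_false(anyDuplicated(names(t1)) > 0)
  keys <- vapply(t1, topology_key, "")
  expect_identical(unname(keys), names(t1))     # canonical keys match names
})

test_that("the candidate table pins the documented topology ids", {
  ot <- order_topologies()
  expect_length(ot, 15L)
  expect_equal(topology_key(ot[["14"]]),
               "((Carnivora,Perissodactyla),(Cetartiodactyla,Chiroptera))")
  expect_equal(topology_key(ot[["8"]]),
               "(((Carnivora,Perissodactyla),Chiroptera),Cetartiodactyla)")
  expect_equal(topology_key(ot[["5"]]),
               "((Carnivora,Chiroptera),(Cetartiodactyla,Perissodactyla))")
  expect_false(anyDuplicated(vapply(ot, topology_key, "")) > 0)
})

test_that("grafting expands orders and restricting inverts it", {
  subs <- list(Carnivora = c("Dog", "Cat", "Panda"),
               Cetartiodactyla = c("Cow", "Dolphin", "Pig", "Alpaca"),
               Chiroptera = c("FlyingFox", "Microbat"),
               Perissodactyla = "Horse")
  order_map <- stats::setNames(
    rep(names(subs), lengths(subs)), unlist(subs))
  for (id in c("14", "5", "1")) {
    full <- graft(order_topologies()[[id]], subs, c("Human", "Mouse"))
    expect_equal(length(full$tip.label), 10L + 2L)
    expect_equal(full$Nnode, length(full$tip.label) - 1L)  # rooted binary
    red <- restrict_to_orders(full, order_map)
    expect_equal(topology_key(red), topology_key(order_topologies()[[id]]))
  }
  ## single-tip subtrees, 2 outgroups -> 6 leaves
  one <- graft(order_topologies()[["14"]],
               as.list(stats::setNames(FOCAL_ORDERS, FOCAL_ORDERS)),
               c("Human", "Mouse"))
  expect_equal(length(one$tip.label), 6L)
  expect_error(graft(order_topologies()[["14"]],
                     list(Carnivora = "Dog"), character()), "no subtree")
})

test_that("species trees from specs honor topology, depth and tip counts", {
  spec <- species_tree_spec(topology_id = 14,
                            within_order_subtrees = list(
                              Carnivora = c("Dog", "Cat", "Panda"),
                              Cetartiodactyla = c("Cow", "Dolphin", "Pig", "Alpaca"),
                              Chiroptera = c("FlyingFox", "Microbat"),
                              Perissodactyla = "Horse"),
                            outgroups = c("Human", "Mouse"))
  tr <- build_species_tree(spec)
  expect_equal(length(tr$tip.label), 12L)
  expect_equal(tr$Nnode, 11L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  order_map <- stats::setNames(
    rep(names(spec$within_order_subtrees), lengths(spec$within_order_subtrees)),
    unlist(spec$within_order_subtrees))
  expect_equal(topology_key(restrict_to_orders(tr, order_map)),
               topology_key(order_topologies()[["14"]]))
  ## identity case: one tip per order, no outgroup
  mini <- build_species_tree(species_tree_spec(topology_id = 5,
                                               outgroups = character()))
  expect_equal(length(mini$tip.label), 4L)
  expect_equal(topology_key(mini), topology_key(order_topologies()[["5"]]))
  expect_error(species_tree_spec(topology_id = 16), "1..15")
  expect_error(species_tree_spec(internal_branch_lengths = c(-1, 1)), ">= 0")
})
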