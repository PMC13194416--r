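# PlantKGR

Inductive link prediction on plant knowledge graphs with a dual-channel
attention network.

## The problem

Plant knowledge graphs store biology as (head, relation, tail) triples:
`(Oryza sativa, in_genus, Oryza)`, `(Pinus massoniana, infected_by,
Bursaphelenchus xylophilus)`. Much of what makes such graphs useful lives in
*long-range* dependencies — associations that only emerge by composing four
or more relation hops, such as the taxonomic chain species → genus → family
→ order → class, or an ecological chain host → pathogen → vector → natural
enemy. Two things make reasoning over these graphs hard:

* **Long paths defeat message-passing GNNs.** Signal dilutes over multiple
  hops, and stacking layers to widen the receptive field homogenizes node
  states (over-smoothing).
* **New species appear constantly.** A practical model must be *inductive*:
  it has to score links in a test graph whose entities were never seen
  during training, so it may not learn per-entity embeddings.

PlantKGR is for researchers who need such a reasoner — and a controlled,
fully synthetic benchmark to study it on — without access to proprietary
plant-KG dumps.

## The model

Given a query `(h, q, ?)`, the network initializes node states
query-conditionally (the head entity's row is set to the embedding of `q`,
every other row to zero — no entity identity is ever used), runs a base
stage of local message passing, then stacks dual-channel layers. Per layer,
for node states `E` and relation states `R`:

* **Global channel** (graph transformer with linear attention): per head,
  `Q = E W_Q`, `K = E W_K`, `V = E W_V`, and the output is
  `φ(Q) (φ(K)ᵀ V)` with the positive kernel `φ(x) = ELU(x) + 1`. The
  key–value summary `φ(K)ᵀV` is formed first, so the cost is `O(2 d² |E|)`
  per head — linear in the number of entities — while being exactly equal
  to the quadratic-order attention `(φ(Q) φ(K)ᵀ) V`. Heads are
  concatenated and projected by `W_m`. An optional row normalization
  divides row `i` by `φ(Q)_i · (φ(K)ᵀ 1)`.
* **Local channel** (attentive relational message passing): for each edge
  into `u`, the message is `m = W_φ (e_v + r)`; attention logits
  `γ = LeakyReLU(W_att m)` are softmax-normalized over the neighborhood
  into weights `β`, and the new local feature is `Σ β m`. Inverse-augmented
  edges (relation `r + |R|`) make propagation bidirectional.
* **Adaptive fusion**: per node, coefficients
  `α_i ∝ exp(LeakyReLU(wᵀ e_i))` over the self, global and local branches
  (summing to 1) produce the fused state `α₁ e_self + α₂ e_glob + α₃
  e_loc`. Relation states update between layers, `R ← R W_rel`.

A triple `(h, q, t)` is scored by `sigmoid(MLP(e_h ‖ r_q ‖ e_t))` (hidden
width 64, ReLU), trained with filtered negative sampling under the loss
`−log p⁺ − (1/n) Σ log(1 − p⁻)` using Adam with L2 weight decay.

Evaluation follows the standard inductive protocol: each test query is
ranked against 49 filtered corrupted tails (pessimistic ties), reporting
Hits@10 and AUC-PR (average precision over pooled scores).

## Worked example

```r
library(PlantKGR)

# a synthetic deep-taxonomy KG: 9 components of 4-hop taxonomy chains,
# ecological chains, decoy clade leaves and power-law noise
gen   <- generatePlantKG(presetGeneratorConfig("taxo-deep", seed = 42))
split <- makeInductiveBenchmark(gen$graph, gen$ruleInstances,
                                partitionConfig(seed = 42))
split
#> InductiveSplit
#>   train graph: 288 entities, 343 triples; 43 train / 5 valid queries
#>   test graph:  114 entities, 129 triples; 19 test queries

avgReachableDistance(trainGraph(split))  #> 4.83 hops
avgReachableDistance(testGraph(split))   #> 5.00 hops  (longer test paths)

mcfg <- modelConfig(dim = 32, nHeads = 4, nTotalLayers = 5,
                    nBaseGnnLayers = 2, normalizeGlobal = TRUE, seed = 42)
tcfg <- trainConfig(nNegatives = 64, batchSize = 16, learningRate = 1e-2,
                    epochs = 20, seed = 42)
fit <- trainModel(split, mcfg, tcfg)
evaluateModel(split, fit$params, seed = 42)
#> EvalReport: Hits@10 = 1.0000, AUC-PR = 0.9946
#>   19 queries, 50 candidates/query, seed 42, AUC-PR pooled
```

The trained model ranks the true 4-hop ancestor of every unseen test
species into the top 10 of its 50-candidate set (Hits@10 = 1.0); AUC-PR
pools the positive scores with one sampled negative each. A one-layer model
on the same benchmark only reaches Hits@10 ≈ 0.5 — it can recognize that a
candidate *looks like* a class-level node but cannot tell which of the many
look-alike roots terminates the query's 4-hop chain — and a model whose
local channel is ablated scores 0.

The same pipeline is scriptable from a shell via `inst/exec/plantkgr.R`
(`generate`, `train`, `evaluate`, `sweep`, `stats` subcommands).

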