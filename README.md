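# drumbeat

Time-resolved probabilistic graph analysis of residue-contact dynamics
in molecular-dynamics (MD) trajectories.

## The problem

MD ensembles of proteins that switch between macro-states — the
canonical example being class A GPCR activation/deactivation — contain
the residue-level events that *enable* and *effect* the transition, but
those events are buried in thousands of fluctuating inter-residue
contacts. `drumbeat` identifies them in a fully data-driven way:

1. **Contact fingerprints.** Each trajectory is encoded as a binary
   matrix `c_i(f) ∈ {0,1}` — contact *i* formed or not at frame *f* —
   parsed from GetContacts-style interaction records.
2. **Feature selection.** Contacts between sequence neighbors are
   excluded, and contacts whose maximum pairwise mutual information
   (MI) with every other contact stays ≤ 0.01 bits are dropped;
   per-trajectory kept sets are combined into the significant set `C`.
3. **Universal dataset.** Trajectories are concatenated, or subsampled
   with replacement from a 5,000-frame region centered at each
   trajectory's transition point (located by a least-squares change
   point on a 1-D transition-proxy trace such as a TM3–TM6 interhelical
   distance), e.g. 1,200 frames × 12 trajectories = 14,400 rows.
4. **Universal graph.** A directed acyclic graph `G = (C, E)` over
   contacts is learned by penalized-likelihood (BIC) hill climbing, so
   `P(C) = Π_i p(c_i | pa_i)`. Edges carry strengths in bits (pairwise
   MI) and each node a weighted degree `D_i = Σ strengths`.
5. **Time-resolved rescoring (the core).** Along each trajectory the
   graph is re-parametrized with sliding-window MI,
   `MI_t(i,j|δ) = H(X_i) + H(X_j) − H(X_i, X_j)` on the window
   `[t−δ, t+δ]`, with δ optimized per edge over a 150–1050-step grid.
   The **TRAC** (Time-Resolved Allosteric Community) trace of contact
   *i* is `D_i(t) = Σ_{j∈Γ_i} MI_t(i,j|δ)`. Peaks in `D_i(t)` mark
   moments of cooperative motion of the community.
6. **Signals.** Contacts are ranked by peak amplitude and prevalence
   across the ensemble; key TRACs must exceed 1 bit in every trajectory
   with at most two peaks each; communities whose first peaks strictly
   precede another's in every trajectory are *enablers*, the others
   *effectors*; connector contacts adjoin both hubs. PCA of the
   enabler+effector subnetwork delineates the conformational states.
7. **Evolution.** Alignment columns are scored with the base-20 Von
   Neumann entropy `S_i = −Σ λ log₂₀ λ` of the density matrix
   `ρ = P^{1/2} S P^{1/2}` (residue frequencies P, BLOSUM50-derived
   similarity S), giving conservation `C_i = 1 − S_i`; positions of a
   residue community are classified as fully conserved or perfectly
   class-specific, summarized by `ρ = log₂ |S|/|C|`.

A seeded synthetic module generates multi-trajectory ensembles with
planted dependency communities and a coordinated macro-transition, plus
toy labeled alignments, so every pipeline stage is testable end to end.

## Worked example

```r
library(drumbeat)

# parse contact records into a binary fingerprint
rec <- read_getcontacts(system.file("extdata", "demo_contacts.tsv",
                                    package = "drumbeat"))
fp <- binarize(rec, n_frames = 30)
colSums(fp$values)
#> A:ASP:130_A:TYR:326 A:ARG:131_A:GLU:268 A:CYS:327_A:PHE:332
#>                  15                  15                  18

# synthetic ensemble with planted enabler/effector communities
syn <- generate_ensemble(n_trajectories = 4, n_frames = 4000, n_contacts = 20,
  communities = list(list(size = 4, coupling = 0.95, role = "enabler"),
                     list(size = 4, coupling = 0.95, role = "effector")),
  t_e = 1500, t_f = 2500, jitter = 150, seed = 42)

fs <- select_features(syn$ensemble)                 # 0.01-bit MI filter
restricted <- lapply(syn$ensemble, restrict_contacts, labels = fs$contacts)
tstars <- vapply(syn$traces, detect_transition, integer(1),
                 smoothing_window = 101)
tstars
#> 2501 2584 2579 2582                               # true switches ~2500

ds <- enriched_sample(restricted, tstars, region = 2500,
                      n_per_traj = 1000, seed = 42)
g <- edge_strengths(learn_structure(ds, seed = 42), ds)
g
#> Universal graph: 14 nodes, 23 directed edges, score -23448.08

traces <- lapply(restricted, trac_traces, graph = g,
                 grid = window_grid(stride = 10))
rk <- rank_contacts(traces, threshold = 1.0)
head(rk$ranking, 5)
#>                 node n_above mean_amplitude
#> 1 A:ALA:31_A:LEU:131       4       2.689331
#> 2 A:ALA:25_A:LEU:125       4       2.638439
#> 3 A:ALA:16_A:LEU:116       4       2.521199
#> 4 A:ALA:28_A:LEU:128       4       2.373409
#> 5 A:ALA:34_A:LEU:134       4       2.280996

pk <- ensemble_peaks(traces, threshold = 1.0)
en <- intersect(rk$ranking$node, syn$truth$communities[[1]])[1]
ef <- intersect(rk$ranking$node, syn$truth$communities[[2]])[1]
classify_order(pk[[en]], pk[[ef]])
#> [1] "a_precedes_b"
```

The top-ranked contacts are exactly the planted community members
(resid 25–34 effector, 13–22 enabler); all exceed 1 bit in 4/4
trajectories, and the enabler representative's first peak precedes the
effector's in every trajectory, reproducing the enabler → effector
ordering the planted ensemble encodes.

The whole workflow can equally be driven from a YAML configuration via
`run_pipeline()` or the thin CLI in `inst/scripts/drumbeat.R`
(`run-all`, `synth`, `evolve` subcommands).

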