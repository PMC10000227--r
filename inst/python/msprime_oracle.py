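"""Independent coalescent oracle based on msprime.

Reads a JSON config on argv[1], simulates the requested demography with
haploid samples and HKY (equal base frequencies = K80) mutations on a
finite discrete genome, and prints mean segregating sites / mean pairwise
differences with their Monte-Carlo standard errors as JSON.

Configs:
  one_deme:  {"model": "one_deme", "N": ..., "n": ..., ...}
  split:     two demes of size N splitting from an ancestor at t_split
  admixture: deme C formed at t_adm from A and B (prop_a), A/B split from
             an ancestor at t_split
Common keys: L, mu (per site per generation), kappa, n_reps, seed.
"""
import json
import sys

import msprime
import numpy as np


def build_demography(cfg):
    model = cfg["model"]
    N = cfg["N"]
    dem = msprime.Demography()
    if model == "one_deme":
        dem.add_population(name="A", initial_size=N)
        samples = {"A": cfg["n"]}
    elif model == "split":
        dem.add_population(name="A", initial_size=N)
        dem.add_population(name="B", initial_size=N)
        dem.add_population(name="ANC", initial_size=cfg.get("N_anc", N))
        dem.add_population_split(time=cfg["t_split"], derived=["A", "B"],
                                 ancestral="ANC")
        samples = {"A": cfg["n"], "B": cfg["n"]}
    elif model == "admixture":
        dem.add_population(name="A", initial_size=N)
        dem.add_population(name="B", initial_size=N)
        dem.add_population(name="C", initial_size=cfg.get("N_c", N))
        dem.add_population(name="ANC", initial_size=cfg.get("N_anc", N))
        dem.add_admixture(time=cfg["t_adm"], derived="C",
                          ancestral=["A", "B"],
                          proportions=[cfg["prop_a"], 1 - cfg["prop_a"]])
        dem.add_population_split(time=cfg["t_split"], derived=["A", "B"],
                                 ancestral="ANC")
        samples = {"A": cfg["n"], "B": cfg["n"], "C": cfg["n"]}
    else:
        raise ValueError(model)
    dem.sort_events()
    return dem, samples


def main():
    cfg = json.loads(sys.argv[1])
    dem, samples = build_demography(cfg)
    L = cfg["L"]
    mu = cfg["mu"]
    kappa = cfg.get("kappa", 10.0)
    rng = np.random.default_rng(cfg.get("seed", 1))
    S = np.empty(cfg["n_reps"])
    k = np.empty(cfg["n_reps"])
    model = msprime.HKY(kappa=kappa)
    for r in range(cfg["n_reps"]):
        ts = msprime.sim_ancestry(
            samples=samples, demography=dem, ploidy=1,
            sequence_length=L, discrete_genome=True,
            random_seed=int(rng.integers(1, 2**31 - 1)))
        mts = msprime.sim_mutations(
            ts, rate=mu, model=model,
            random_seed=int(rng.integers(1, 2**31 - 1)))
        S[r] = mts.segregating_sites(span_normalise=False, mode="site")
        k[r] = mts.diversity(span_normalise=False, mode="site")
    out = {
        "mean_S": float(S.mean()),
        "se_S": float(S.std(ddof=1) / np.sqrt(len(S))),
        "mean_k": float(k.mean()),
        "se_k": float(k.std(ddof=1) / np.sqrt(len(k))),
        "n_reps": int(cfg["n_reps"]),
    }
    print(json.dumps(out))


if __name__ == "__main__":
    main()
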