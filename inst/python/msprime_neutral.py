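"""Neutral coalescent-with-recombination sampler (msprime backend).

Writes ms-style text: one // block per replicate with segsites: and
positions: lines. Parameter conventions match the R package: haploid
population size N, theta = 2*N*mu*L, rho = 2*N*r_bp*L, alpha = 2*N*r
(growth), so pairwise coalescence time has mean N generations.
"""
import argparse
import sys

import msprime
import numpy as np


def main():
    p = argparse.ArgumentParser()
    p.add_argument("--n", type=int, required=True)
    p.add_argument("--theta", type=float, required=True)
    p.add_argument("--rho", type=float, default=0.0)
    p.add_argument("--alpha", type=float, default=0.0)
    p.add_argument("--N", type=float, default=20000.0)
    p.add_argument("--L", type=float, default=50000.0)
    p.add_argument("--reps", type=int, required=True)
    p.add_argument("--seed", type=int, required=True)
    p.add_argument("--out", default="-")
    a = p.parse_args()

    mu = a.theta / (2.0 * a.N * a.L)
    r_bp = a.rho / (2.0 * a.N * a.L)
    demog = msprime.Demography()
    # growth_rate g gives N(t) = N0 * exp(-g t) backwards in time
    demog.add_population(initial_size=a.N,
                         growth_rate=(a.alpha / (2.0 * a.N)))

    rng = np.random.default_rng(a.seed)
    seeds = rng.integers(1, 2**31 - 1, size=2 * a.reps)

    out = sys.stdout if a.out == "-" else open(a.out, "w")
    out.write(f"ms {a.n} {a.reps}\n0 0 0\n\n")
    for i in range(a.reps):
        ts = msprime.sim_ancestry(
            samples={0: a.n}, ploidy=1, demography=demog,
            sequence_length=a.L, recombination_rate=r_bp,
            random_seed=int(seeds[2 * i]))
        mts = msprime.sim_mutations(
            ts, rate=mu, model=msprime.BinaryMutationModel(),
            discrete_genome=False, random_seed=int(seeds[2 * i + 1]))
        G = mts.genotype_matrix()          # S x n
        pos = mts.tables.sites.position / a.L
        w = G.sum(axis=1)
        keep = (w > 0) & (w < a.n)
        G = G[keep]
        pos = pos[keep]
        out.write("//\n")
        out.write(f"segsites: {G.shape[0]}\n")
        if G.shape[0]:
            out.write("positions: "
                      + " ".join(f"{x:.10f}" for x in pos) + "\n")
            rows = (G.T.astype(np.uint8) + ord("0")).tobytes()
            S = G.shape[0]
            for h in range(a.n):
                out.write(rows[h * S:(h + 1) * S].decode("ascii"))
                out.write("\n")
        out.write("\n")
    if out is not sys.stdout:
        out.close()


if __name__ == "__main__":
    main()
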