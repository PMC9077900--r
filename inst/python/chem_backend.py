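"""RDKit backend for the offpanel R package.

Reads a tab-separated file of (index, smiles) records and writes one
tab-separated result row per input row:

    idx ok error canonical_smiles mw logp hbd hba rotb mr polarizability
    lipinski_failures fp

Standardization is RDKit's MolStandardize cleanup, followed by largest-fragment
(salt/solvent strip) and charge neutralization; the parent structure is
re-parsed from its canonical SMILES before property calculation. Fingerprints
are binary Morgan fingerprints of radius 2 (ECFP4 diameter convention) folded
to --nbits bits and emitted as a 0/1 character string. Polarizability is
estimated from the Crippen molar refractivity via the Lorentz-Lorenz relation,
alpha [A^3] = (3 / 4 pi N_A) * MR [cm^3/mol] = 0.3964308 * MR.
"""

import argparse
import csv
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, Lipinski, rdFingerprintGenerator
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

ALPHA_PER_MR = 3.0 / (4.0 * math.pi * 6.02214076e23) * 1e24  # A^3 per cm^3/mol


def standardize(mol):
    mol = rdMolStandardize.Cleanup(mol)
    mol = rdMolStandardize.FragmentParent(mol)
    mol = rdMolStandardize.Uncharger().uncharge(mol)
    # round-trip so ring info / aromaticity are freshly sanitized
    return Chem.MolFromSmiles(Chem.MolToSmiles(mol))


def lipinski_failures(mol):
    return sum(
        [
            Descriptors.MolWt(mol) > 500.0,
            Crippen.MolLogP(mol) > 5.0,
            Lipinski.NumHDonors(mol) > 5,
            Lipinski.NumHAcceptors(mol) > 10,
        ]
    )


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--infile", required=True)
    ap.add_argument("--outfile", required=True)
    ap.add_argument("--fp", action="store_true", help="emit fingerprint bits")
    ap.add_argument("--radius", type=int, default=2)
    ap.add_argument("--nbits", type=int, default=1024)
    ap.add_argument("--no-standardize", action="store_true")
    args = ap.parse_args()

    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=args.radius, fpSize=args.nbits
    )
    cols = [
        "idx", "ok", "error", "canonical_smiles", "mw", "logp", "hbd", "hba",
        "rotb", "mr", "polarizability", "lipinski_failures", "fp",
    ]
    with open(args.infile, newline="") as fin, open(args.outfile, "w", newline="") as fout:
        writer = csv.writer(fout, delimiter="\t", lineterminator="\n")
        writer.writerow(cols)
        for row in csv.reader(fin, delimiter="\t"):
            if not row:
                continue
            idx, smi = row[0], row[1]
            out = {"idx": idx, "ok": 0, "error": "", "canonical_smiles": ""}
            try:
                mol = Chem.MolFromSmiles(smi)
                if mol is None:
                    raise ValueError("unparsable SMILES")
                if not args.no_standardize:
                    mol = standardize(mol)
                    if mol is None:
                        raise ValueError("standardization failed")
                out["canonical_smiles"] = Chem.MolToSmiles(mol)
                mr = Crippen.MolMR(mol)
                out.update(
                    ok=1,
                    mw="%.6f" % Descriptors.MolWt(mol),
                    logp="%.6f" % Crippen.MolLogP(mol),
                    hbd=Lipinski.NumHDonors(mol),
                    hba=Lipinski.NumHAcceptors(mol),
                    rotb=Lipinski.NumRotatableBonds(mol),
                    mr="%.6f" % mr,
                    polarizability="%.6f" % (ALPHA_PER_MR * mr),
                    lipinski_failures=lipinski_failures(mol),
                )
                if args.fp:
                    out["fp"] = gen.GetFingerprint(mol).ToBitString()
            except Exception as exc:  # record, never abort the batch
                out["error"] = str(exc).replace("\t", " ").replace("\n", " ")
            writer.writerow([out.get(c, "") for c in cols])
    return 0


if __name__ == "__main__":
    sys.exit(main())
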