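# Last names used by the synthetic narrative generator. Includes surnames
# that collide with medical eponyms and common words (Johnson, Stevens,
# Parkinson, Graves) so the disambiguation problem is represented.
# One name per line; all entries longer than 3 characters.
Smith
Patel
Rosling
Kaveson
Johnson
Stevens
Parkinson
Graves
Sharma
Okafor
Nilsson
Hussain
Zhang
Kowalski
Petrov
Tanaka
Mensah
Williams
Browne
Murphy
Adeyemi
Chowdhury
Lindqvist
Fernandez
Haraldsen
Nakamura
Acheampong
Delacroix
Szymanski
Thackeray
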