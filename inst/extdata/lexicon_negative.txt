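# Bundled general-purpose negative sentiment lexicon (one token per line).
# Written for this package; deliberately disjoint from the positive list.
afraid
angry
annoyed
anxious
ashamed
awful
bad
bitter
bleak
bored
broken
cranky
craving
cruel
crying
damage
danger
dead
defeated
depressed
desperate
difficult
dirty
disappointed
discouraged
disgusted
dismal
distress
doubt
dread
dreadful
edgy
exhausted
fail
failure
fear
fearful
fight
frustrated
gloomy
grief
grim
grumpy
guilt
guilty
harm
harsh
hate
headache
helpless
hopeless
horrible
hurt
irritable
irritated
jittery
lonely
lost
mad
miserable
misery
moody
mourn
nasty
nausea
negative
nervous
pain
painful
panic
pathetic
poor
regret
relapse
restless
rotten
sad
scared
shaky
sick
sore
sorrow
sorry
stress
stressed
struggle
struggling
stuck
suffer
suffering
terrible
tired
toxic
tragic
trouble
ugly
unbearable
uneasy
unhappy
upset
weak
weary
worse
worst
worried
worry
wretched
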