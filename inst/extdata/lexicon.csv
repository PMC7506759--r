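word,pos,lemma
a,det,a
an,det,an
and,det,and
animal,noun,animal
ape,noun,ape
apple,noun,apple
are,verb,are
asian,adj,asian
at,prep,at
baby,noun,baby
bag,noun,bag
ball,noun,ball
banana,noun,banana
barbecue,noun,barbecue
be,verb,be
beach,noun,beach
bear,noun,bear
bed,noun,bed
bee,noun,bee
beef,noun,beef
bicycle,noun,bicycle
big,adj,big
bird,noun,bird
black,adj,black
blue,adj,blue
boat,noun,boat
boiled,adj,boiled
book,noun,book
bottle,noun,bottle
bowl,noun,bowl
box,noun,box
braised,adj,braised
branch,noun,branch
bread,noun,bread
bridge,noun,bridge
brown,adj,brown
building,noun,building
bush,noun,bush
butterfly,noun,butterfly
by,prep,by
cabbage,noun,cabbage
cake,noun,cake
camera,noun,camera
candy,noun,candy
car,noun,car
cat,noun,cat
category,noun,category
chair,noun,chair
cheese,noun,cheese
chicken,noun,chicken
child,noun,child
children,noun,child
chinese,adj,chinese
chocolate,noun,chocolate
clock,noun,clock
cloud,noun,cloud
cockatoo,noun,cockatoo
coin,noun,coin
cold,adj,cold
computer,noun,computer
cooked,adj,cooked
cow,noun,cow
crab,noun,crab
crow,noun,crow
cup,noun,cup
curry,noun,curry
deer,noun,deer
dhole,noun,dhole
dish,noun,dish
dog,noun,dog
door,noun,door
dried,adj,dried
duck,noun,duck
dumpling,noun,dumpling
dunlin,noun,dunlin
eagle,noun,eagle
ear,noun,ear
eat,verb,eat
egg,noun,egg
elephant,noun,elephant
eye,noun,eye
feet,noun,foot
fish,noun,fish
flower,noun,flower
food,noun,food
foot,noun,foot
forest,noun,forest
fork,noun,fork
fox,noun,fox
fresh,adj,fresh
fried,adj,fried
frog,noun,frog
from,prep,from
fruit,noun,fruit
fungi,noun,fungus
fungus,noun,fungus
game,noun,game
garlic,noun,garlic
geese,noun,goose
gibbon,noun,gibbon
glass,noun,glass
go,verb,go
goat,noun,goat
goose,noun,goose
grape,noun,grape
grass,noun,grass
gray,adj,gray
green,adj,green
group,noun,group
gull,noun,gull
hand,noun,hand
has,verb,has
hat,noun,hat
have,verb,have
hawk,noun,hawk
head,noun,head
hen,noun,hen
horse,noun,horse
hot,adj,hot
house,noun,house
image,noun,image
in,prep,in
insect,noun,insect
intestine,noun,intestine
is,verb,is
it,det,it
jacamar,noun,jacamar
jackal,noun,jackal
key,noun,key
keyboard,noun,keyboard
kitchen,noun,kitchen
kitten,noun,kitten
knife,noun,knife
knives,noun,knife
know,verb,know
label,noun,label
lake,noun,lake
lamb,noun,lamb
lamp,noun,lamp
large,adj,large
leaf,noun,leaf
leaves,noun,leaf
leg,noun,leg
letter,noun,letter
library,noun,library
like,verb,like
lion,noun,lion
little,adj,little
lizard,noun,lizard
lock,noun,lock
look,verb,look
make,verb,make
man,noun,man
market,noun,market
meat,noun,meat
meatball,noun,meatball
mice,noun,mouse
milk,noun,milk
mold,noun,mold
money,noun,money
monkey,noun,monkey
moon,noun,moon
mountain,noun,mountain
mouse,noun,mouse
mushroom,noun,mushroom
music,noun,music
noodle,noun,noodle
object,noun,object
ocean,noun,ocean
of,prep,of
office,noun,office
old,adj,old
on,prep,on
onion,noun,onion
or,det,or
orange,noun,orange
ostrich,noun,ostrich
over,prep,over
owl,noun,owl
page,noun,page
paper,noun,paper
parrot,noun,parrot
pasta,noun,pasta
peacock,noun,peacock
pen,noun,pen
pencil,noun,pencil
penguin,noun,penguin
people,noun,person
pepper,noun,pepper
person,noun,person
phone,noun,phone
photo,noun,photo
picture,noun,picture
pig,noun,pig
pigeon,noun,pigeon
plane,noun,plane
plant,noun,plant
plate,noun,plate
pork,noun,pork
puppy,noun,puppy
rabbit,noun,rabbit
rat,noun,rat
raw,adj,raw
red,adj,red
rice,noun,rice
river,noun,river
road,noun,road
roasted,adj,roasted
rock,noun,rock
room,noun,room
rooster,noun,rooster
root,noun,root
run,verb,run
salad,noun,salad
salty,adj,salty
sauce,noun,sauce
school,noun,school
screen,noun,screen
seafood,noun,seafood
see,verb,see
seed,noun,seed
sheep,noun,sheep
shelf,noun,shelf
shirt,noun,shirt
shoe,noun,shoe
shop,noun,shop
shredded,adj,shredded
shrimp,noun,shrimp
siamang,noun,siamang
sign,noun,sign
site,noun,site
sky,noun,sky
small,adj,small
snail,noun,snail
snake,noun,snake
some,det,some
song,noun,song
soup,noun,soup
sour,adj,sour
sparrow,noun,sparrow
spicy,adj,spicy
spider,noun,spider
spoon,noun,spoon
squid,noun,squid
squirrel,noun,squirrel
star,noun,star
steamed,adj,steamed
stew,noun,stew
stir,adj,stir
stone,noun,stone
store,noun,store
street,noun,street
sun,noun,sun
swan,noun,swan
sweet,adj,sweet
table,noun,table
tail,noun,tail
tame,adj,tame
text,noun,text
that,det,that
the,det,the
thing,noun,thing
think,verb,think
this,det,this
tiger,noun,tiger
to,prep,to
toadstool,noun,toadstool
tofu,noun,tofu
toy,noun,toy
train,noun,train
tree,noun,tree
truck,noun,truck
truffle,noun,truffle
turkey,noun,turkey
under,prep,under
vegetable,noun,vegetable
want,verb,want
was,verb,was
watch,noun,watch
website,noun,website
white,adj,white
wild,adj,wild
window,noun,window
wing,noun,wing
with,prep,with
wolf,noun,wolf
wolves,noun,wolf
woman,noun,woman
word,noun,word
yeast,noun,yeast
yellow,adj,yellow
young,adj,young
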